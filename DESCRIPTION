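Package: pipemri
Title: Protocol-Independent Parameter Estimation for Spherical-Convolution Diffusion MRI
Version: 0.1.0
Authors@R:
    person("PIPE", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates microstructure parameters of spherical-convolution diffusion MRI
    models (e.g. the white-matter Standard Model) when gradient nonlinearities give every
    voxel a different effective diffusion protocol. The fiber-response rotational
    invariants are factorized by singular value decomposition into protocol-dependent
    basis functions, interpolated in b with Chebyshev polynomials, and tissue-dependent
    coefficients; per-voxel linear projection yields protocol-free gamma coefficients,
    and a train-once polynomial regressor maps their rotational invariants to kernel
    parameters and fODF anisotropy. Includes gradient-coil tensor field utilities
    (effective b-values and directions, nonlinearity invariants), a synthetic phantom
    generator with spatially varying protocols, NIfTI/bval/bvec input-output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
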