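# Shared fixtures, built once per test run and memoized. Sizes are scaled
# down from the method's full-scale defaults (50000 x 1000) to keep the suite fast;
# accuracy at these sizes is itself asserted in test-factorization.R and
# test-acceptance.R.

.fixtures <- new.env(parent = emptyenv())

# internal helper used across test files (visible regardless of whether
# tests run inside the package namespace)
unit_rows <- pipemri:::unit_rows

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

fix_library <- function() memo("lib", function()
  build_library(n_xi = 2000, n_b = 128, seed = 1))

# pipeline default: identifiable on three-shell protocols
fix_basis <- function() memo("basis43", function()
  svd_factorize(fix_library(), n_comp = c(4, 3)))

fix_basis5 <- function() memo("basis5", function()
  svd_factorize(fix_library(), n_comp = 5))

fix_protocol <- function() memo("protocol", function() shelled_protocol())

fix_protocol_g <- function() as.matrix(fix_protocol()[, c("gx", "gy", "gz")])

# regressor trained once at SNR 50 with the shelled reference protocol
fix_regressor <- function() memo("reg50", function() {
  prot <- fix_protocol()
  ts <- make_training_set(
    fix_basis(), 15000,
    noise = list(kind = "snr", snr = 50, b = prot$b, g = fix_protocol_g()),
    seed = 11)
  suppressWarnings(fit_polynomial(ts, W = 3))
})

# one kernel-parameter set + band-limited fODF used across tests
fix_xi <- function() sm_params(0.55, 2.1, 1.9, 0.8, 0.15)

fix_xi_table <- function()
  data.frame(f = 0.55, Da = 2.1, Depar = 1.9, Deperp = 0.8, fw = 0.15)

fix_fodf2 <- function() memo("fodf2", function() sample_fodf(1, seed = 42, lmax = 2))

random_rotation <- function() {
  e <- sample_so3_uniform(1)
  euler_zyz(e$alpha, e$beta, e$gamma)
}
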