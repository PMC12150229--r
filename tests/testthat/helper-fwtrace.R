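# shared fixtures, built in code

# axially symmetric eigenvalues with a target FA at fixed MD
evals_for_fa <- function(fa, md = 0.7e-3) {
  if (fa == 0) return(rep(md, 3))
  g <- function(r) {
    l1 <- 3 * md * r / (r + 2)
    l2 <- 3 * md / (r + 2)
    c(l1, l2, l2)
  }
  froot <- function(r) {
    l <- g(r); m <- mean(l)
    sqrt(1.5 * sum((l - m)^2) / sum(l^2)) - fa
  }
  g(stats::uniroot(froot, c(1.0001, 500))$root)
}

# small single-cohort study for model tests
tiny_atlas <- function(tracts = c("fornix", "cingulum", "SLF",
                                  "corticospinal_tract", "TC_SPL", "TC_V1")) {
  at <- atlas_registry()
  at[at$tract %in% tracts, , drop = FALSE]
}

no_batch_truth <- function(...) {
  args <- list(gamma_batch = c(A_b1 = 0), delta_batch = c(A_b1 = 1),
               phi_endo = c(hippocampal_volume = 0, spare_ad = 0,
                            amyloid_positive = 0, tau_positive = 0),
               phi_endo_cross = c(hippocampal_volume = 0, spare_ad = 0,
                                  amyloid_positive = 0, tau_positive = 0))
  override <- list(...)
  args[names(override)] <- override
  do.call(truth_params, args)
}

one_cohort <- function(n = 200, visits = 3, interval = 1.4, name = "A") {
  list(cohort_config(name, n, 74, 7, visits, interval))
}
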