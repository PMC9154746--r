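# Shared fixtures, built in code. The shipped 3- and 20-component targets
# stand in for denoised MSMS profiles of low and high complexity.

shipped_target <- function(which = c("3gmm", "20gmm")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("synthetic_target_%s.tsv", which),
                      package = "golgicode")
  read_glycan_profile(path, normalize = TRUE)
}

# small system + in-box parameter draw used across tests
tiny_system <- function(NC = 2, NE = 2, Ns = 40, ...) {
  golgi_system(NC = NC, NE = NE, Ns = Ns, ...)
}

random_params <- function(system, sigma = 1, seed = 1) {
  make_recovery_fixture(system, sigma, seed)$params
}

validate_params_ok <- function(system, params) {
  mb <- system$mu_bounds
  rb <- system$R_bounds
  all(params$mu >= mb[1] & params$mu <= mb[2]) &&
    all(params$R >= rb[1] & params$R <= rb[2]) &&
    all(params$L >= 1 & params$L <= system$Ns)
}

# uniform-rate promiscuous parameter set (sigma = 0, one enzyme)
uniform_params <- function(NC, R, mu, Ns) {
  parameter_set(mu = rep(mu, NC), R = matrix(R, 1, NC),
                L = matrix(1, 1, NC), sigma = 0)
}
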