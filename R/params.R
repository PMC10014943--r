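#' Kinetic parameter sets for the Rac-Rho-paxillin models
#'
#' `kinetic_params()` builds a validated parameter set for the 6V, 2V and 4V
#' Rac-Rho-paxillin models. Values not supplied are taken from the packaged
#' default configuration, which was calibrated so that the four-variable model
#' reproduces the qualitative regime structure of the system: mixed-mode
#' oscillations at the default `L_K = 5.77`, relaxation oscillations when
#' `L_K` is lowered towards 4.5, and a stable steady state when `L_K` is
#' raised towards 7.
#'
#' The slow-dynamics parameters must respect the three-timescale ordering
#' `eps_L < eps < 1`: Rac kinetics are fast, the maximum paxillin
#' phosphorylation rate `B` is slow, and its recovery rate `k_B` is very slow.
#'
#' @param ... named parameter overrides, e.g. `L_K = 4.5`. Unknown names are
#'   an error.
#' @param file optional path to a YAML file with a complete parameter set; by
#'   default the packaged configuration is used. A file missing any required
#'   parameter is a load error, never silently completed.
#' @return an object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params(L_K = 4.5)
#' p$L_K
#' @export
kinetic_params <- function(..., file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "kinetic_params.yaml", package = "racpax",
                        mustWork = TRUE)
  }
  p <- yaml::read_yaml(file)
  missing <- setdiff(.param_names, names(p))
  if (length(missing)) {
    stop("parameter file ", file, " is missing required parameters: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- p[.param_names]
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    bad <- setdiff(names(over), .param_names)
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(over)] <- over
  }
  validate_kinetic_params(p)
}

.param_names <- c(
  "n", "L_rho", "L_R", "L_K", "I_R", "I_rho", "I_K",
  "delta_R", "delta_rho", "delta_P", "gamma", "alpha_P", "alpha_R",
  "k_X", "k_G", "k_C", "GIT", "PIX", "Pax_tot", "B",
  "eps", "eps_L", "eps_B", "eta", "B_r", "gamma_R", "gamma_K",
  "D_R", "D_Ri", "D_rho", "D_rhoi", "D_P", "D_Pi"
)

validate_kinetic_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("non-numeric or non-finite parameter(s): ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  nonneg <- setdiff(.param_names, "gamma_K")  # gamma_K is a Rac level target
  neg <- nonneg[unlist(p[nonneg]) < 0]
  if (length(neg)) {
    stop("parameter(s) must be nonnegative: ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  if (p$n < 1) stop("Hill coefficient n must be >= 1", call. = FALSE)
  if (!(p$eps_L < p$eps && p$eps < 1)) {
    stop("three-timescale ordering violated: need eps_L < eps < 1 (got eps_L = ",
         p$eps_L, ", eps = ", p$eps, ")", call. = FALSE)
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Rac-Rho-paxillin kinetic parameters\n")
  cat(sprintf("  L_K = %g, B_r = %g, eps = %g, eps_L = %g\n",
              x$L_K, x$B_r, x$eps, x$eps_L))
  cat("  ", length(x), "parameters; see names() for the full set\n")
  invisible(x)
}
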