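#' Load a packaged or user-supplied profile scenario
#'
#' A scenario bundles a [profile_model()], default chart settings and
#' (optionally) a grid of study shifts.  Three fixtures ship with the
#' package:
#' \describe{
#'   \item{\code{"p2_sim"}}{the two-response simulation scenario:
#'     \eqn{y_1 = 3 + 2x_1 + x_2 + \epsilon_1},
#'     \eqn{y_2 = 2 + x_1 + x_2 + \epsilon_2}, error covariance
#'     \eqn{\Sigma_0 = [[1, 0.5], [0.5, 1]]}, fixed design matrices for
#'     \eqn{n = 4} and \eqn{n = 8}.}
#'   \item{\code{"stroke"}}{thrombolysis delay-time monitoring: base-10
#'     log onset-to-needle and door-to-needle times regressed on age, sex
#'     and stroke severity, with the fitted Phase-I coefficients and error
#'     covariance; covariates are drawn per sample (no fixed design).}
#'   \item{\code{"p6_sim"}}{the six-response scenario.  Its source case does
#'     not publish the design matrices or error covariance, so the fixture
#'     ships with an empty design map (supply your own \code{X}) and a
#'     synthetic equicorrelation-0.5, unit-variance covariance.}
#' }
#'
#' @param name a fixture name above, or the path of a scenario YAML file.
#' @return An object of class \code{"profile_scenario"}: list with
#'   \code{name}, \code{model}, \code{cfg}, \code{shift_grid},
#'   \code{covariates}, \code{response_scale}, \code{notes}.
#' @export
load_scenario <- function(name) {
  builtin <- c("p2_sim", "stroke", "p6_sim")
  file <- if (name %in% builtin) {
    system.file("extdata", paste0(name, ".yaml"), package = "vpcharts",
                mustWork = TRUE)
  } else if (file.exists(name)) {
    name
  } else {
    stop("unknown scenario \"", name, "\"; available fixtures: ",
         paste(builtin, collapse = ", "),
         " (or pass the path of a scenario YAML file)")
  }
  read_scenario(file)
}

#' Read a scenario from a YAML file
#'
#' The file must define \code{q}, \code{p}, \code{B} (list of q+1 rows of p
#' values), \code{Sigma} (p rows), and may define \code{designs} (map from
#' sample size to an n x (q+1) matrix given as rows), a \code{chart} block
#' with [chart_config()] fields, a \code{shift_grid}, a \code{covariates}
#' block for stream generation, \code{response_scale} and \code{notes}.
#'
#' @param file path of the YAML file.
#' @return A \code{"profile_scenario"}.
#' @export
read_scenario <- function(file) {
  y <- yaml::read_yaml(file)
  to_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))
  B <- to_mat(y$B)
  Sigma <- to_mat(y$Sigma)
  if (nrow(B) != y$q + 1L || ncol(B) != y$p)
    stop("B must be (q+1) x p in ", file)
  designs <- lapply(y$designs %||% list(), to_mat)
  model <- profile_model(B, Sigma, designs, name = y$name %||% basename(file))
  cfg <- do.call(chart_config, c(y$chart %||% list()))
  structure(list(name = model$name, model = model, cfg = cfg,
                 shift_grid = y$shift_grid, covariates = y$covariates,
                 design = y$design,
                 response_scale = y$response_scale %||% "identity",
                 notes = y$notes %||% ""),
            class = "profile_scenario")
}

#' Write a scenario to a YAML file
#'
#' @param scenario a \code{"profile_scenario"}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_scenario <- function(scenario, file) {
  m <- scenario$model
  rows <- function(M) apply(unname(as.matrix(M)), 1L, as.numeric,
                            simplify = FALSE)
  y <- list(name = scenario$name, q = m$q, p = m$p,
            B = rows(m$B), Sigma = rows(m$Sigma),
            designs = lapply(m$designs, rows),
            chart = scenario$cfg[c("lam", "k1", "k2", "tau_design",
                                   "clamp_eps")],
            shift_grid = scenario$shift_grid,
            covariates = scenario$covariates,
            design = scenario$design,
            response_scale = scenario$response_scale,
            notes = scenario$notes)
  yaml::write_yaml(y, file)
  invisible(file)
}

#' @export
print.profile_scenario <- function(x, ...) {
  cat("Profile scenario \"", x$name, "\"\n", sep = "")
  print(x$model)
  if (nzchar(x$notes)) cat("  ", trimws(x$notes), "\n", sep = "")
  invisible(x)
}
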