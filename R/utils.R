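#' @keywords internal
"_PACKAGE"

#' @importFrom stats median optimize quantile rlnorm rnorm runif sd setNames
#'   cor lm coef dnorm pnorm
#' @importFrom utils read.csv write.csv head tail
NULL

# Trapezoidal integral on a (possibly non-uniform) grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Trapezoidal node weights: integral(y) == sum(w * y) on the grid.
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

# Overflow-safe cosh((L - x)/l) / cosh(L/l), the closed-form shape of a
# diffusion-decay steady state with influx at x = 0 and a sealed tip at x = L.
cosh_profile <- function(x, L, l) {
  # cosh((L-x)/l)/cosh(L/l) = exp(-x/l) * (1 + exp(-2(L-x)/l)) / (1 + exp(-2L/l))
  exp(-x / l) * (1 + exp(-2 * (L - x) / l)) / (1 + exp(-2 * L / l))
}

# Deterministic memo key from numeric parameters.
solve_key <- function(...) {
  paste(vapply(list(...), function(v) paste(signif(v, 12), collapse = ","),
               character(1)), collapse = "|")
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("dendrocost_config_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("dendrocost_numeric_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a bundled or user configuration file
#'
#' Configuration is stored as YAML. The package ships two files under
#' `inst/extdata/`: `grid_levels.yaml` (the three sampled values per parameter
#' dimension of the synthetic species grid) and `defaults.yaml` (geometry,
#' transport and cost constants).
#'
#' @param name file name of a bundled config (`"grid_levels.yaml"` or
#'   `"defaults.yaml"`), or a path to a user file.
#' @return a nested list.
#' @export
read_config <- function(name = "defaults.yaml") {
  path <- if (file.exists(name)) name else
    system.file("extdata", name, package = "dendrocost")
  if (!nzchar(path) || !file.exists(path))
    stop_config("config file not found: ", name)
  yaml::read_yaml(path)
}
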