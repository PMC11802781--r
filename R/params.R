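#' Exponential-decay rate from a half-life
#'
#' @param halflife half-life in seconds (strictly positive).
#' @return decay rate `log(2)/halflife` in 1/s.
#' @examples
#' decay_rate(log(2))   # 1
#' decay_rate(72000)    # a ~20 h mRNA
#' @export
decay_rate <- function(halflife) {
  if (!is.numeric(halflife) || any(!is.finite(halflife)) || any(halflife <= 0))
    stop_config("half-life must be a positive finite number")
  log(2) / halflife
}

#' Motor transport parameters
#'
#' Describes bidirectional run-and-pause transport: molecules in a resting,
#' diffusive state re-enter each moving state (anterograde/retrograde, speed
#' `v`) with rate `alpha` and terminate runs with rate `beta`. The steady-state
#' transported fraction is `theta = 2*alpha/(2*alpha + beta)`; either `alpha`
#' or `theta` may be given.
#'
#' @param v instantaneous run velocity (um/s).
#' @param beta run termination rate (1/s); `1/beta` is the mean run duration.
#' @param alpha re-entry rate into each moving state (1/s).
#' @param theta transported fraction in `[0, 1)`; used to derive `alpha` when
#'   `alpha` is missing.
#' @param v_bias optional net anterograde drift (um/s) applied to the
#'   effective one-state mRNA equation.
#' @return an object of class `transport_params`.
#' @export
transport_params <- function(v = 1, beta = 0.5, alpha = NULL, theta = NULL,
                             v_bias = 0) {
  if (beta <= 0) stop_config("beta must be > 0 (runs must terminate)")
  if (v < 0) stop_config("v must be >= 0")
  if (is.null(alpha)) {
    theta <- theta %||% 0
    if (theta < 0 || theta >= 1) stop_config("theta must lie in [0, 1)")
    alpha <- beta * theta / (2 * (1 - theta))
  }
  if (alpha < 0) stop_config("alpha must be >= 0")
  structure(
    list(v = v, beta = beta, alpha = alpha,
         theta = transported_fraction(alpha, beta), v_bias = v_bias),
    class = "transport_params")
}

#' Dendrite geometry
#'
#' @param L dendrite length (um), soma at `x = 0`, sealed tip at `x = L`.
#' @param rho spine density (spines/um).
#' @param phi minimal spine filling ratio at equilibrium, in `(0, 1)`.
#' @param grid_dx spatial discretisation step (um); must divide `L`.
#' @return an object of class `dendrite_geometry`.
#' @export
dendrite_geometry <- function(L = 250, rho = 1, phi = 0.95, grid_dx = 1) {
  if (L <= 0) stop_config("L must be > 0")
  if (phi <= 0 || phi >= 1) stop_config("phi must lie strictly in (0, 1)")
  if (rho <= 0) stop_config("rho must be > 0")
  if (grid_dx <= 0 || abs(L / grid_dx - round(L / grid_dx)) > 1e-8)
    stop_config("grid_dx must be positive and divide L")
  structure(list(L = L, rho = rho, phi = phi, grid_dx = grid_dx),
            class = "dendrite_geometry")
}

#' Molecular species parameters
#'
#' Bundles every per-species quantity of the model: half-lives (degradation
#' rates are derived as `log(2)/halflife`), molecule lengths, diffusion
#' constants, spine exchange rates and capacity, and motor transport
#' parameters.
#'
#' @param name species identifier.
#' @param D_m0 diffusion constant of non-transported mRNA (um^2/s).
#' @param D_p protein diffusion constant (um^2/s).
#' @param halflife_m mRNA half-life (s).
#' @param halflife_p protein half-life (s).
#' @param tau translation rate (proteins per mRNA per s).
#' @param eta_p maximal protein copies per spine.
#' @param u_p spine entry rate (1/s).
#' @param nu_p spine exit rate (1/s).
#' @param N_aa protein length (amino acids).
#' @param N_nt transcript length in nucleotides (coding + non-coding); must be
#'   at least `3 * N_aa`. Defaults to `3 * N_aa * (1 + noncoding_ratio)`.
#' @param noncoding_ratio non-coding/coding nucleotide ratio; derived from
#'   `N_nt` when that is given.
#' @param transport a [transport_params()] object.
#' @param mrnas_per_granule mRNA copies per transport granule.
#' @param labels optional named character vector of grid group labels.
#' @return an object of class `species_params` with derived fields `lambda_m`,
#'   `lambda_p`.
#' @export
species_params <- function(name = "species",
                           D_m0 = 0.005, D_p = 0.05,
                           halflife_m = 36000, halflife_p = 691200,
                           tau = 0.01, eta_p = 1000,
                           u_p = 1e-3, nu_p = 1e-4,
                           N_aa = 450, N_nt = NULL, noncoding_ratio = NULL,
                           transport = transport_params(),
                           mrnas_per_granule = 1, labels = NULL) {
  if (is.null(N_nt)) {
    noncoding_ratio <- noncoding_ratio %||% 1
    N_nt <- 3 * N_aa * (1 + noncoding_ratio)
  } else {
    noncoding_ratio <- N_nt / (3 * N_aa) - 1
  }
  for (nm in c("D_m0", "D_p", "halflife_m", "halflife_p", "tau", "eta_p",
               "u_p", "nu_p", "N_aa", "N_nt", "mrnas_per_granule")) {
    v <- get(nm)
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      stop_config("species '", name, "': ", nm, " must be a positive number")
  }
  if (N_nt < 3 * N_aa - 1e-9)
    stop_config("species '", name, "': N_nt must be >= 3 * N_aa")
  if (!inherits(transport, "transport_params"))
    stop_config("transport must be a transport_params object")
  structure(
    list(name = name, D_m0 = D_m0, D_p = D_p,
         halflife_m = halflife_m, halflife_p = halflife_p,
         lambda_m = decay_rate(halflife_m), lambda_p = decay_rate(halflife_p),
         tau = tau, eta_p = eta_p, u_p = u_p, nu_p = nu_p,
         N_aa = N_aa, N_nt = N_nt, noncoding_ratio = noncoding_ratio,
         transport = transport, mrnas_per_granule = mrnas_per_granule,
         labels = labels),
    class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species_params> %s\n", x$name))
  cat(sprintf("  mRNA: half-life %.3g h, %d nt (noncoding ratio %.2g), D_m0 %.3g um^2/s\n",
              x$halflife_m / 3600, round(x$N_nt), x$noncoding_ratio, x$D_m0))
  cat(sprintf("  protein: half-life %.3g d, %d aa, D_p %.3g um^2/s\n",
              x$halflife_p / 86400, round(x$N_aa), x$D_p))
  cat(sprintf("  spines: eta_p %.4g, u_p %.3g /s, nu_p %.3g /s\n",
              x$eta_p, x$u_p, x$nu_p))
  cat(sprintf("  transport: v %.3g um/s, alpha %.4g /s, beta %.3g /s (theta %.3g)\n",
              x$transport$v, x$transport$alpha, x$transport$beta,
              x$transport$theta))
  invisible(x)
}

preset_from_config <- function(key) {
  cfg <- read_config("defaults.yaml")
  p <- cfg$presets[[key]]
  if (is.null(p)) stop_config("no preset '", key, "' in defaults.yaml")
  tr <- p$transport
  species_params(
    name = p$name, D_m0 = p$D_m0, D_p = p$D_p,
    halflife_m = p$halflife_m, halflife_p = p$halflife_p,
    tau = p$tau, eta_p = p$eta_p, u_p = p$u_p, nu_p = p$nu_p,
    N_aa = p$N_aa, N_nt = p$N_nt,
    transport = transport_params(v = tr$v, beta = tr$beta, theta = tr$theta))
}

#' CaMKII-alpha species preset
#'
#' The worked example of the energy framework: a 478-aa synaptic kinase with a
#' ~4900-nt transcript, ~20 h mRNA half-life, ~8 d protein half-life, a
#' translation rate of 0.01 proteins per mRNA per second and ~32336 copies per
#' spine. Diffusion, spine-exchange and transport values are provisional
#' literature-range defaults from `defaults.yaml`.
#'
#' @return a [species_params()] object.
#' @export
camkii_preset <- function() preset_from_config("camkii")

#' Shank3 species preset (photoactivation paradigm)
#'
#' Parameters for the somatically synthesised scaffold protein used in the
#' photoactivation simulation. Values marked provisional in `defaults.yaml`.
#'
#' @return a [species_params()] object.
#' @export
shank3_preset <- function() preset_from_config("shank3")

#' Full-factorial synthetic species grid
#'
#' Builds the Cartesian product of three values per parameter dimension
#' (default: the seven bundled dimensions, giving `3^7 = 2187` species). Each
#' species carries a low/medium/high group label per dimension.
#'
#' @param levels named list of per-dimension numeric level vectors (exactly 3
#'   values each); defaults to the bundled `grid_levels.yaml`.
#' @param fixed named list overriding the fixed (non-sampled) defaults
#'   (`tau`, `u_p`, `nu_p`, `D_m0`, `v`, `beta`, `mrnas_per_granule`).
#' @return a list of [species_params()], in deterministic (row-major,
#'   first dimension fastest) order, with a `grid_labels` attribute: a
#'   data.frame of group labels (`"low"`, `"medium"`, `"high"`) per dimension.
#' @export
grid_sample <- function(levels = NULL, fixed = list()) {
  if (is.null(levels)) {
    cfg <- read_config("grid_levels.yaml")
    levels <- lapply(cfg$dimensions, function(d) as.numeric(d$levels))
  }
  if (!length(levels) || is.null(names(levels)) || any(!nzchar(names(levels))))
    stop_config("levels must be a named list")
  bad <- names(levels)[vapply(levels, length, 1L) != 3L]
  if (length(bad))
    stop_config("each dimension needs exactly 3 values; offending: ",
                paste(bad, collapse = ", "))
  def <- read_config("defaults.yaml")
  fx <- utils::modifyList(list(
    tau = def$rates$tau, u_p = def$rates$u_p, nu_p = def$rates$nu_p,
    D_m0 = def$diffusion$D_m0, D_p = def$diffusion$D_p,
    v = def$transport$v, beta = def$transport$beta,
    mrnas_per_granule = def$scenario$mrnas_per_granule), fixed)

  idx <- do.call(expand.grid, c(lapply(levels, function(l) 1:3),
                                KEEP.OUT.ATTRS = FALSE))
  lab_names <- c("low", "medium", "high")
  labels <- as.data.frame(lapply(idx, function(i) lab_names[i]),
                          stringsAsFactors = FALSE)
  species <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    val <- mapply(function(l, i) l[i], levels, as.integer(idx[r, ]))
    g <- function(dim, default) if (dim %in% names(val)) val[[dim]] else default
    theta <- g("transport_theta", 0)
    species[[r]] <- species_params(
      name = sprintf("S%04d", r),
      D_m0 = fx$D_m0,
      D_p = g("protein_diffusion", fx$D_p),
      halflife_m = g("mrna_halflife", 36000),
      halflife_p = g("protein_halflife", 691200),
      tau = fx$tau,
      eta_p = g("spine_capacity", 1000),
      u_p = fx$u_p, nu_p = fx$nu_p,
      N_aa = g("protein_aa", 450),
      noncoding_ratio = g("noncoding_ratio", 1),
      transport = transport_params(v = fx$v, beta = fx$beta, theta = theta),
      mrnas_per_granule = fx$mrnas_per_granule,
      labels = setNames(as.character(labels[r, ]), names(levels)))
  }
  attr(species, "grid_labels") <- labels
  species
}

#' Write species parameters to a delimited text table
#'
#' @param species a list of [species_params()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_species_table <- function(species, path) {
  rows <- lapply(species, function(s) data.frame(
    name = s$name, D_m0 = s$D_m0, D_p = s$D_p,
    halflife_m = s$halflife_m, halflife_p = s$halflife_p,
    tau = s$tau, eta_p = s$eta_p, u_p = s$u_p, nu_p = s$nu_p,
    N_aa = s$N_aa, N_nt = s$N_nt,
    v = s$transport$v, beta = s$transport$beta, alpha = s$transport$alpha,
    v_bias = s$transport$v_bias,
    mrnas_per_granule = s$mrnas_per_granule,
    stringsAsFactors = FALSE))
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read species parameters from a delimited text table
#'
#' Expects the header written by [write_species_table()].
#'
#' @param path CSV/TSV path.
#' @return a list of [species_params()].
#' @export
read_species_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("name", "D_m0", "D_p", "halflife_m", "halflife_p", "tau", "eta_p",
            "u_p", "nu_p", "N_aa", "N_nt", "v", "beta", "alpha")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_config("species table misses columns: ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop_config("species table is empty")
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    species_params(
      name = as.character(r$name), D_m0 = r$D_m0, D_p = r$D_p,
      halflife_m = r$halflife_m, halflife_p = r$halflife_p,
      tau = r$tau, eta_p = r$eta_p, u_p = r$u_p, nu_p = r$nu_p,
      N_aa = r$N_aa, N_nt = r$N_nt,
      transport = transport_params(
        v = r$v, beta = r$beta, alpha = r$alpha,
        v_bias = if ("v_bias" %in% names(df)) r$v_bias else 0),
      mrnas_per_granule = if ("mrnas_per_granule" %in% names(df))
        r$mrnas_per_granule else 1)
  })
}
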