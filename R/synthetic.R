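#' Condition presets for the synthetic-data generator
#'
#' Each experimental condition (awake, light/deep anaesthesia, thalamic-DBS
#' states) is emulated by a per-mode coefficient profile over the harmonic
#' modes of the structural connectome: `global_sd` scales the uniform
#' zero-eigenvalue mode (a shared whole-cortex signal driving functional
#' integration), `modular_sd` scales the low-frequency modular modes
#' (2 to 8), `fine_sd` the remaining high-frequency modes, and `noise_sd`
#' adds isotropic measurement noise. The shipped constants (a versioned JSON
#' resource) are calibrated so that, relative to awake, deep anaesthesia
#' carries relatively more coefficient mass on high-spatial-frequency
#' (high-eigenvalue) modes and less on the global/modular ones - raising
#' scan-level harmonic energy while lowering hierarchical integration and
#' gradient range, the directions the markers are designed to detect.
#' High-amplitude centro-median DBS is close to awake, low-amplitude between
#' light and deep, and ventro-lateral DBS indistinguishable from
#' unstimulated anaesthesia.
#'
#' @param name Preset name: one of `"awake"`, `"light_anaesthesia"`,
#'   `"deep_anaesthesia"`, `"dbs_off"`, `"ct_low"`, `"ct_high"`, `"vt_low"`,
#'   `"vt_high"`.
#' @return An object of class `condition_preset` with fields `name`,
#'   `global_sd`, `modular_sd`, `fine_sd`, `noise_sd`, `arousal_score`.
#' @examples
#' condition_preset("awake")
#' @export
condition_preset <- function(name) {
  path <- system.file("extdata", "condition_presets.json",
                      package = "eigenmarkers", mustWork = TRUE)
  all <- jsonlite::read_json(path, simplifyVector = TRUE)$presets
  if (!name %in% names(all))
    stop("unknown preset `", name, "`; available: ",
         paste(names(all), collapse = ", "))
  p <- all[[name]]
  structure(c(list(name = name), p), class = "condition_preset")
}

#' @export
print.condition_preset <- function(x, ...) {
  cat("Condition preset `", x$name, "`: global_sd=", x$global_sd,
      ", modular_sd=", x$modular_sd, ", fine_sd=", x$fine_sd,
      ", noise_sd=", x$noise_sd, ", arousal=", x$arousal_score, "\n",
      sep = "")
  invisible(x)
}

# Per-mode coefficient standard deviations implied by a preset, for a basis
# of n modes (ascending eigenvalue): mode 1 global, modes 2..8 modular,
# remainder fine-grained.
preset_sigma <- function(preset, n) {
  n_mod <- min(7L, n - 1L)
  sigma <- c(preset$global_sd,
             rep(preset$modular_sd, n_mod),
             rep(preset$fine_sd, max(0L, n - 1L - n_mod)))
  sigma[seq_len(n)]
}

#' Generate a modular weighted structural connectome
#'
#' Builds a synthetic stand-in for a parcellated macaque-style connectome: a
#' dense, symmetric, non-negative weighted graph with `n_modules` blocks of
#' regions, within-module weights centred on `within_strength` and
#' between-module weights on `between_strength`, each jittered by a
#' multiplicative uniform factor of half-width `weight_noise`. If the
#' requested parameters leave the graph disconnected (e.g. zero
#' between-module strength), bridge edges linking consecutive modules are
#' added with a warning.
#'
#' @param n_regions Number of regions (>= 4; the study parcellation has 82).
#' @param n_modules Number of modules (default 4).
#' @param within_strength,between_strength Mean within/between-module weight;
#'   `within_strength > between_strength > 0` expected.
#' @param weight_noise Relative jitter half-width in `[0, 1)` (default 0.3).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A [symmetrize_connectome()] result.
#' @export
generate_connectome <- function(n_regions = 82L, n_modules = 4L,
                                within_strength = 1, between_strength = 0.1,
                                seed = 1L, weight_noise = 0.3) {
  if (n_regions < 4L) stop("need at least 4 regions")
  if (within_strength <= 0) stop("within_strength must be > 0")
  if (within_strength <= between_strength)
    stop("within_strength must exceed between_strength")
  set.seed(seed)
  module <- rep(seq_len(n_modules), length.out = n_regions)
  module <- sort(module)
  base <- ifelse(outer(module, module, `==`), within_strength,
                 between_strength)
  jitter <- matrix(stats::runif(n_regions^2, 1 - weight_noise,
                                1 + weight_noise), n_regions)
  w <- base * jitter
  w <- (w + t(w)) / 2
  diag(w) <- 0
  labels <- sprintf("R%02d_M%d", seq_len(n_regions), module)

  deg <- rowSums(w)
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                           diag = FALSE)
  if (any(deg == 0) || igraph::components(g)$no > 1L) {
    warning("generated graph was disconnected; adding bridge edges ",
            "between consecutive modules")
    for (m in seq_len(n_modules - 1L)) {
      i <- max(which(module == m)); j <- min(which(module == m + 1L))
      w[i, j] <- w[j, i] <- within_strength / 2
    }
  }
  symmetrize_connectome(w, region_labels = labels)
}

#' Generate a parcellated BOLD run from a harmonic basis
#'
#' Draws a run directly in harmonic coordinates: each mode's coefficient
#' series is i.i.d. Gaussian with the per-mode standard deviation implied by
#' the preset (or supplied directly), the timepoints are reconstructed as
#' `F_t = sum_k omega_k(t) phi_k`, and isotropic Gaussian noise of standard
#' deviation `noise_sd` is added. This is the minimal statistical structure
#' the markers assume - a controllable energy-versus-spatial-frequency
#' profile - not a biophysical haemodynamic simulation.
#'
#' @param basis A [compute_harmonic_basis()] result.
#' @param preset A [condition_preset()] or a numeric vector of per-mode
#'   standard deviations of length equal to the number of modes.
#' @param T_ Number of timepoints (default 500).
#' @param tr Repetition time in seconds (default 1.25).
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation; defaults to the preset's value
#'   (0 when `preset` is a raw sigma vector).
#' @param meta Extra metadata merged into the run sidecar.
#' @return A [parcellated_ts()].
#' @export
generate_timeseries <- function(basis, preset, T_ = 500L, tr = 1.25,
                                seed = 1L, noise_sd = NULL, meta = list()) {
  stopifnot(inherits(basis, "harmonic_basis"))
  n <- length(basis$eigenvalues)
  if (T_ < 2L) stop("need at least 2 timepoints")
  if (inherits(preset, "condition_preset")) {
    sigma <- preset_sigma(preset, n)
    if (is.null(noise_sd)) noise_sd <- preset$noise_sd
    cond <- preset$name
  } else {
    sigma <- as.numeric(preset)
    if (length(sigma) != n)
      stop("sigma vector length (", length(sigma),
           ") must equal number of modes (", n, ")")
    if (any(sigma < 0)) stop("per-mode standard deviations must be >= 0")
    if (is.null(noise_sd)) noise_sd <- 0
    cond <- meta$condition %||% "custom"
  }
  set.seed(seed)
  omega <- matrix(stats::rnorm(T_ * n), T_, n)
  omega <- sweep(omega, 2L, sigma, `*`)
  x <- omega %*% t(basis$eigenvectors)
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), sd = noise_sd)
  meta <- utils::modifyList(list(condition = cond, seed = seed), meta)
  parcellated_ts(x, tr = tr, region_labels = basis$region_labels, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic study on disk
#'
#' Writes a complete dataset in the pipeline's input layout: a shared
#' `connectome.tsv`, one TSV + JSON sidecar per run under `runs/`, and an
#' `arousal.csv` mapping each run to its condition's behavioural score.
#' Animal labels are cycled over runs within each condition. Fully
#' deterministic given `seed` (per-run seeds are derived from it and
#' recorded in the sidecars).
#'
#' @param dir Output directory (created if missing).
#' @param conditions Character vector of preset names (>= 2).
#' @param runs_per_condition Runs per condition (default 4).
#' @param animals Character vector of animal labels (default 3 animals).
#' @param n_regions,T_,tr Study dimensions (defaults 82 regions, 500
#'   timepoints, TR 1.25 s).
#' @param seed Master integer seed.
#' @param dataset Dataset label written into sidecars.
#' @return `dir`, invisibly.
#' @export
generate_study <- function(dir,
                           conditions = c("awake", "light_anaesthesia",
                                          "deep_anaesthesia", "dbs_off",
                                          "ct_low", "ct_high"),
                           runs_per_condition = 4L,
                           animals = c("A", "K", "J"),
                           n_regions = 82L, T_ = 500L, tr = 1.25,
                           seed = 1L, dataset = "synthetic") {
  if (length(conditions) < 2L) stop("need at least 2 conditions")
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed) %% 100000L
  sc <- generate_connectome(n_regions = n_regions, seed = seed)
  write_connectome(sc, file.path(dir, "connectome.tsv"))
  basis <- compute_harmonic_basis(build_normalized_laplacian(sc))

  rows <- list()
  run_id <- 0L
  for (ci in seq_along(conditions)) {
    preset <- condition_preset(conditions[ci])
    for (r in seq_len(runs_per_condition)) {
      run_id <- run_id + 1L
      run_seed <- seed * 10000L + run_id
      animal <- animals[((r - 1L) %% length(animals)) + 1L]
      ts <- generate_timeseries(
        basis, preset, T_ = T_, tr = tr, seed = run_seed,
        meta = list(dataset = dataset, animal = animal,
                    run = sprintf("run%03d", run_id)))
      write_timeseries(ts, file.path(dir, "runs",
                                     sprintf("run%03d.tsv", run_id)))
      rows[[run_id]] <- data.frame(
        run = sprintf("run%03d", run_id), dataset = dataset,
        animal = animal, condition = preset$name,
        arousal_score = preset$arousal_score)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "arousal.csv"),
                   row.names = FALSE)
  invisible(dir)
}
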