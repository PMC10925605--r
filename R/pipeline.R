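#' Compute all distributed markers for every run of a dataset
#'
#' Orchestrates the full marker pipeline over a dataset directory laid out as
#' written by [generate_study()]: `connectome.tsv`, `runs/*.tsv` with JSON
#' sidecars, and optionally `arousal.csv`. For each run it (optionally)
#' band-pass/notch filters and regresses the global signal, then computes the
#' scan-level harmonic energy on the shared structural basis, the functional
#' gradient markers from diffusion map embedding, and the hierarchical
#' integration/segregation of the FC eigenmodes. Runs that fail an invariant
#' are skipped with a warning; the call errors only if every run fails.
#'
#' @param dir Dataset directory.
#' @param filter,gsr Logical preprocessing switches (defaults off: synthetic
#'   and already-cleaned parcellated input need neither; set both for raw
#'   extracted series, which matches the study preprocessing of
#'   filter-then-GSR).
#' @param low_cut,high_cut,notch Filter parameters, see [temporal_filter()].
#' @param density,alpha,kernel,n_components Gradient parameters, see
#'   [build_affinity()] and [diffusion_map_embedding()].
#' @return A `data.frame` with one row per run: identifiers (`run`,
#'   `dataset`, `animal`, `condition`), markers (`gradient_range`,
#'   `gradient_range2`, `gradient_dispersion`, `eigenvalue_ratio`,
#'   `hierarchical_integration`, `hierarchical_segregation`,
#'   `harmonic_energy`) and `arousal_score`.
#' @export
run_markers <- function(dir, filter = FALSE, gsr = FALSE,
                        low_cut = 0.0025, high_cut = 0.05, notch = 0.03,
                        density = 0.10, alpha = 0.5,
                        kernel = "normalized_angle", n_components = 10L) {
  sc <- read_connectome(file.path(dir, "connectome.tsv"))
  basis <- compute_harmonic_basis(build_normalized_laplacian(sc))
  run_files <- sort(list.files(file.path(dir, "runs"), pattern = "\\.tsv$",
                               full.names = TRUE))
  if (length(run_files) == 0L) stop("no runs found under ", dir)

  arousal_map <- NULL
  arousal_csv <- file.path(dir, "arousal.csv")
  if (file.exists(arousal_csv)) {
    ar <- read_arousal_csv(arousal_csv)
    arousal_map <- stats::setNames(ar$arousal_score, ar$run)
  }

  rows <- list()
  for (f in run_files) {
    row <- tryCatch({
      ts <- read_timeseries(f)
      if (filter) ts <- temporal_filter(ts, low_cut, high_cut, notch)
      if (gsr) ts <- regress_global_signal(ts)

      spec <- decompose_timeseries(ts, basis)
      fc <- compute_fc(ts)
      emb <- diffusion_map_embedding(
        build_affinity(fc, density = density, kernel = kernel),
        alpha = alpha, n_components = n_components)
      hier <- hierarchy_decomposition(fc)

      run_name <- ts$meta$run %||% sub("\\.tsv$", "", basename(f))
      score <- if (!is.null(arousal_map) && run_name %in% names(arousal_map))
        arousal_map[[run_name]]
      else condition_arousal(ts$meta$condition %||% "awake")
      data.frame(
        run = run_name,
        dataset = ts$meta$dataset %||% "dataset1",
        animal = ts$meta$animal %||% NA_character_,
        condition = ts$meta$condition %||% NA_character_,
        gradient_range = gradient_range(emb, 1L),
        gradient_range2 = gradient_range(emb, 2L),
        gradient_dispersion = gradient_dispersion(emb, 3L),
        eigenvalue_ratio = principal_eigenvalue_ratio(emb),
        hierarchical_integration = hier$h_in,
        hierarchical_segregation = hier$h_se,
        harmonic_energy = scan_energy(spec),
        arousal_score = score,
        stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("skipping run ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) stop("all runs failed; no markers computed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Brain-behaviour dominance analysis of a marker table
#'
#' Links the distributed markers to the behavioural arousal score: markers
#' are min-max normalised within each dataset (so datasets acquired with
#' different scanners can be pooled), a dominance analysis partitions the
#' regression fit among the markers, and a permutation test assesses the
#' full-model fit against randomly reassigned arousal scores. When `cutoff`
#' is given, arousal is dichotomised at that threshold and the
#' classification variant (logistic regression, McFadden pseudo-R-squared)
#' is run instead.
#'
#' @param table Marker table from [run_markers()] (or equivalent), with an
#'   `arousal_score` column and a `dataset` column.
#' @param predictors Marker columns to use (default: principal gradient
#'   range, hierarchical integration, harmonic energy).
#' @param n_perm Permutations for the significance test (default 1000).
#' @param seed Integer seed for the permutation null.
#' @param cutoff Optional dichotomisation threshold (9 or 3 in the study
#'   design).
#' @param fit_metric Fit metric for the dominance decomposition of the
#'   continuous-response variant (`"r2"` or `"adj_r2"`).
#' @return List of class `brain_behaviour_result`: `dominance` (a
#'   [dominance_analysis()] result), `permutation` (a
#'   [permutation_test_r2()] result; omitted for the classification
#'   variant), `table` (the normalised table), `predictors`, `cutoff`.
#' @export
run_brain_behaviour <- function(table,
                                predictors = c("gradient_range",
                                               "hierarchical_integration",
                                               "harmonic_energy"),
                                n_perm = 1000L, seed = 1L, cutoff = NULL,
                                fit_metric = "r2") {
  stopifnot(is.data.frame(table), "arousal_score" %in% names(table))
  missing_cols <- setdiff(predictors, names(table))
  if (length(missing_cols))
    stop("marker table lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  norm <- normalize_markers(table, markers = predictors)
  X <- as.matrix(norm[, predictors, drop = FALSE])
  if (is.null(cutoff)) {
    y <- norm$arousal_score
    dom <- dominance_analysis(X, y, fit_metric = fit_metric)
    perm <- permutation_test_r2(X, y, n_perm = n_perm, seed = seed,
                                fit_metric = if (fit_metric == "adj_r2")
                                  "adj_r2" else "r2")
  } else {
    y <- dichotomize_arousal(norm$arousal_score, cutoff = cutoff)
    dom <- dominance_analysis(X, y, fit_metric = "mcfadden")
    perm <- NULL
  }
  structure(list(dominance = dom, permutation = perm, table = norm,
                 predictors = predictors, cutoff = cutoff),
            class = "brain_behaviour_result")
}

#' @export
print.brain_behaviour_result <- function(x, ...) {
  cat("Brain-behaviour dominance analysis",
      if (!is.null(x$cutoff)) paste0("(classification, cutoff ", x$cutoff, ")"),
      "\n")
  print(x$dominance)
  if (!is.null(x$permutation))
    cat("  permutation p =", signif(x$permutation$p_value, 4), "over",
        x$permutation$n_perm, "permutations\n")
  invisible(x)
}
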