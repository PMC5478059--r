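apply_estimators <- function(mat, estimators) {
  fits <- list()
  for (e in estimators) {
    fits[[e]] <- switch(e,
      gst = gst_migration(mat),
      inference = inference_migration(mat),
      etienne1 = onestage_migration(mat),
      etienne2 = twostage_migration(mat),
      stop("unknown estimator: ", e))
  }
  fits
}

#' Parameter-recovery experiment on the spatially implicit model
#'
#' For each migration value on a grid, simulates the spatially implicit
#' model and estimates migration back with the chosen estimators; summarizes
#' the mean absolute difference between given and estimated migration per
#' estimator.
#'
#' @param meta a [logseries_metacommunity()] object.
#' @param m_grid migration values in (0, 1].
#' @param estimators subset of `c("gst", "inference", "etienne1",
#'   "etienne2")`.
#' @param n_plots,J,generations simulation scale (see [implicit_config()]).
#' @param replicates independent simulation replicates per grid point.
#' @return List with `cells` (one row per m x estimator x replicate:
#'   `m_given`, `estimator`, `replicate`, `m_mean`, `m_sd`) and `summary`
#'   (per estimator: `delta_m = mean |m_mean - m_given|` over cells).
#' @export
recovery_experiment <- function(meta, m_grid,
                                estimators = c("gst", "inference"),
                                n_plots = 20, J = 625, generations = 200,
                                replicates = 3) {
  stopifnot(all(m_grid > 0), all(m_grid <= 1), replicates >= 1)
  cells <- data.frame()
  for (m in m_grid) {
    cfg <- implicit_config(n_plots, J, m, generations)
    for (rep in seq_len(replicates)) {
      mat <- run_implicit(meta, cfg)
      fits <- apply_estimators(mat, estimators)
      for (e in names(fits)) {
        cells <- rbind(cells, data.frame(
          m_given = m, estimator = e, replicate = rep,
          m_mean = fits[[e]]$mean, m_sd = fits[[e]]$sd))
      }
    }
  }
  agg <- stats::aggregate(cbind(m_mean) ~ m_given + estimator, cells, mean)
  agg$abs_err <- abs(agg$m_mean - agg$m_given)
  summ <- stats::aggregate(abs_err ~ estimator, agg, mean)
  names(summ)[2] <- "delta_m"
  list(cells = cells, by_m = agg, summary = summ)
}

#' Additivity experiment on the semi-explicit lattice model
#'
#' Runs one lattice simulation per `(m_adj, m_meta)` scenario and reports the
#' pooled species and singleton counts together with each estimator's joint
#' migration estimate; the spatially implicit estimators can only see the sum
#' `m_adj + m_meta`, and underestimate it when adjacent-plot migration
#' dominates.
#'
#' @param meta a [logseries_metacommunity()] object.
#' @param scenarios data frame with columns `m_adj` and `m_meta`.
#' @param estimators subset of `c("gst", "inference", "etienne1",
#'   "etienne2")`.
#' @param rows,cols,J,generations,edge lattice scale (see
#'   [lattice_config()]).
#' @return Data frame: one row per scenario with `m_local`, `m_adj`,
#'   `m_meta`, `m_joint`, `species`, `singletons`, then `<estimator>_mean`
#'   and `<estimator>_sd` columns.
#' @export
additivity_experiment <- function(meta, scenarios,
                                  estimators = c("gst", "inference"),
                                  rows = 20, cols = 20, J = 500,
                                  generations = 200, edge = "torus") {
  stopifnot(all(c("m_adj", "m_meta") %in% names(scenarios)))
  out <- data.frame()
  for (i in seq_len(nrow(scenarios))) {
    ma <- scenarios$m_adj[i]; mm <- scenarios$m_meta[i]
    cfg <- lattice_config(rows, cols, J, ma, mm, generations, edge)
    mat <- run_lattice(meta, cfg)
    tot <- colSums(mat)
    row <- data.frame(m_local = 1 - ma - mm, m_adj = ma, m_meta = mm,
                      m_joint = ma + mm,
                      species = sum(tot > 0), singletons = sum(tot == 1))
    fits <- apply_estimators(mat, estimators)
    for (e in names(fits)) {
      row[[paste0(e, "_mean")]] <- fits[[e]]$mean
      row[[paste0(e, "_sd")]] <- fits[[e]]$sd
      row[[paste0(e, "_mean_raw")]] <- fits[[e]]$mean_raw
    }
    out <- rbind(out, row)
  }
  out
}

#' Emulate a field dataset with the spatially implicit model
#'
#' Runs the spatially implicit model at a migration value previously
#' estimated from field data and summarizes the simulated dataset the way
#' field inventories are summarized: pooled species and singleton counts,
#' Fisher's alpha and the pooled rank-abundance distribution. The returned
#' community matrix is the synthetic field dataset.
#'
#' @param meta a [logseries_metacommunity()] object (the regional pool the
#'   emulated region is assumed to draw from).
#' @param n_plots,J,generations simulation scale.
#' @param m migration probability in (0, 1].
#' @return List with `matrix` (the plots x species `community_matrix`),
#'   `species`, `singletons`, `mean_alpha` (per-plot Fisher's alpha,
#'   averaged), `pooled_alpha`, and `rad` (pooled descending relative
#'   abundances).
#' @export
field_emulation <- function(meta, n_plots, J = 625, m, generations = 200) {
  stopifnot(m > 0, m <= 1)
  cfg <- implicit_config(n_plots, J, m, generations)
  mat <- run_implicit(meta, cfg)
  rs <- rad_summary(mat)
  list(matrix = mat, species = rs$species, singletons = rs$singletons,
       mean_alpha = rs$mean_alpha, pooled_alpha = rs$pooled_alpha,
       rad = rs$rad)
}

#' Rank-abundance and diversity summary of a community matrix
#'
#' @param mat plots x species count matrix.
#' @return List with `species` and `singletons` (pooled), `rad` (pooled
#'   descending relative abundances), `plot_alpha` (per-plot Fisher's alpha;
#'   `NA` and flagged for plots with `S == J` or `S <= 1`), `mean_alpha`,
#'   and `pooled_alpha`.
#' @export
rad_summary <- function(mat) {
  mat <- as.matrix(mat)
  if (length(mat) == 0 || sum(mat) == 0) stop("empty community matrix")
  tot <- colSums(mat)
  S <- sum(tot > 0)
  N <- sum(tot)
  rad <- sort(tot[tot > 0], decreasing = TRUE) / N
  plot_alpha <- apply(mat, 1, function(r) {
    Jk <- sum(r); Sk <- sum(r > 0)
    if (Sk <= 1 || Sk >= Jk) return(NA_real_)
    fishers_alpha(Jk, Sk)
  })
  list(species = S, singletons = sum(tot == 1),
       rad = unname(rad),
       plot_alpha = plot_alpha,
       mean_alpha = mean(plot_alpha, na.rm = TRUE),
       pooled_alpha = if (S >= 2 && S < N) fishers_alpha(N, S) else NA_real_)
}
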