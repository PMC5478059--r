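#' Configuration for the spatially implicit local-community model
#'
#' @param n_plots number of independent local communities.
#' @param J individuals per plot (default 625, one-hectare-plot convention).
#' @param m migration probability: each recruit's parent is drawn from the
#'   metacommunity with probability `m`, from the local plot otherwise.
#' @param generations run length in generations; one generation is `J`
#'   death/replacement events per plot (default 200, which plateaus all
#'   configurations used here; see [stationarity_trace()]).
#' @return A list of class `implicit_config`.
#' @export
implicit_config <- function(n_plots, J = 625, m, generations = 200) {
  stopifnot(n_plots >= 1, J >= 2, m >= 0, m <= 1, generations >= 0)
  structure(list(n_plots = as.integer(n_plots), J = as.integer(J), m = m,
                 generations = generations),
            class = "implicit_config")
}

#' Configuration for the spatially semi-explicit lattice model
#'
#' Plots sit on a `rows` x `cols` lattice. Each replacement event recruits
#' from one of three sources with a discrete probability mass function:
#' a Moore-adjacent plot (`m_adj`), the metacommunity (`m_meta`), or the
#' local plot (`1 - m_adj - m_meta`).
#'
#' @param rows,cols lattice dimensions (default 20 x 20).
#' @param J individuals per plot (default 500).
#' @param m_adj probability of recruitment from one of the eight adjacent
#'   plots (neighbor plot chosen uniformly, then a parent in proportion to
#'   that plot's abundances).
#' @param m_meta probability of recruitment from the metacommunity.
#' @param generations run length in generations (J events per plot).
#' @param edge `"torus"` (default; every plot has eight neighbors and the
#'   lattice is statistically homogeneous) or `"truncated"` (edge and corner
#'   plots have 5 or 3 neighbors).
#' @return A list of class `lattice_config`.
#' @export
lattice_config <- function(rows = 20, cols = 20, J = 500, m_adj, m_meta,
                           generations = 200,
                           edge = c("torus", "truncated")) {
  edge <- match.arg(edge)
  stopifnot(rows >= 1, cols >= 1, rows * cols >= 2, J >= 2,
            m_adj >= 0, m_meta >= 0, generations >= 0)
  if (m_adj + m_meta > 1)
    stop("m_adj + m_meta must not exceed 1")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 J = as.integer(J), m_adj = m_adj, m_meta = m_meta,
                 generations = generations, edge = edge),
            class = "lattice_config")
}

#' Moore neighborhood of a lattice cell
#'
#' Indices (1-based, column-major over the `rows` x `cols` lattice) of the
#' up-to-eight cells surrounding a focal cell.
#'
#' @param row,col focal cell coordinates (1-based).
#' @param rows,cols lattice dimensions.
#' @param edge `"torus"` wraps around (always 8 distinct neighbors when the
#'   lattice is at least 3 x 3); `"truncated"` drops off-lattice cells
#'   (3 for a corner, 5 for an edge, 8 for an interior cell).
#' @return Integer vector of plot indices.
#' @export
neighbor_indices <- function(row, col, rows, cols,
                             edge = c("torus", "truncated")) {
  edge <- match.arg(edge)
  if (row < 1 || row > rows || col < 1 || col > cols)
    stop("cell (", row, ",", col, ") outside ", rows, "x", cols, " lattice")
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  r <- row + off$dr
  c <- col + off$dc
  if (edge == "torus") {
    r <- (r - 1) %% rows + 1
    c <- (c - 1) %% cols + 1
  } else {
    keep <- r >= 1 & r <= rows & c >= 1 & c <= cols
    r <- r[keep]; c <- c[keep]
  }
  idx <- unique(as.integer((c - 1) * rows + r))
  # on lattices narrower than 3 cells the torus wrap can map an offset back
  # onto the focal cell; the neighborhood never includes the plot itself
  setdiff(idx, as.integer((col - 1) * rows + row))
}

# 8 x n_plots neighbor index matrix (0-based for C++) plus per-plot counts
neighbor_table <- function(rows, cols, edge) {
  n <- rows * cols
  nb <- matrix(0L, 8, n)
  cnt <- integer(n)
  for (cc in seq_len(cols)) {
    for (rr in seq_len(rows)) {
      p <- (cc - 1) * rows + rr
      v <- neighbor_indices(rr, cc, rows, cols, edge) - 1L
      cnt[p] <- length(v)
      nb[seq_along(v), p] <- v
    }
  }
  list(nb = nb, cnt = cnt)
}

as_community_matrix <- function(counts, meta, coords = NULL) {
  colnames(counts) <- meta$species
  rownames(counts) <- sprintf("plot%03d", seq_len(nrow(counts)))
  if (!is.null(coords)) attr(counts, "coords") <- coords
  class(counts) <- c("community_matrix", class(counts))
  counts
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community matrix: %d plots x %d species (%d present), J = %s\n",
              nrow(x), ncol(x), sum(colSums(x) > 0),
              paste(unique(range(rowSums(x))), collapse = "-")))
  invisible(x)
}

#' Run the spatially implicit neutral model
#'
#' Zero-sum Moran dynamics in independent plots: each plot is initialized as
#' a random metacommunity sample of size `J`; at every event one individual
#' dies and is replaced by the offspring of a parent drawn from the
#' metacommunity (probability `m`) or uniformly from the `J - 1` surviving
#' locals (probability `1 - m`).
#'
#' @param meta a [logseries_metacommunity()] object.
#' @param config an [implicit_config()].
#' @param init optional `J x n_plots` integer matrix of 1-based species
#'   indices to resume from.
#' @param keep_state return the individual-level state for chained runs.
#' @return A `community_matrix` (plots x species integer counts). Attributes:
#'   `sources` (tally of recruitment sources), and `state` if requested.
#' @export
run_implicit <- function(meta, config, init = NULL, keep_state = FALSE) {
  stopifnot(inherits(meta, "logseries_meta"),
            inherits(config, "implicit_config"))
  cum <- cumsum(meta$abundance / meta$N)
  if (!is.null(init)) init <- init - 1L
  res <- .sim_implicit_engine(cum, config$n_plots, config$J, config$m,
                              config$generations * config$J, init)
  out <- as_community_matrix(res$counts, meta)
  attr(out, "sources") <- res$sources
  if (keep_state) attr(out, "state") <- res$state + 1L
  out
}

#' Run the spatially semi-explicit lattice model
#'
#' Zero-sum Moran dynamics on a lattice of plots. Events are scheduled as
#' sweeps: each sweep kills one uniformly chosen individual in every plot
#' and replaces it by a recruit whose source is drawn from the PMF
#' `{local: 1 - m_adj - m_meta, adjacent: m_adj, metacommunity: m_meta}`.
#'
#' @inheritParams run_implicit
#' @param config a [lattice_config()].
#' @return A `community_matrix` with a `coords` attribute giving each plot's
#'   lattice row and column.
#' @export
run_lattice <- function(meta, config, init = NULL, keep_state = FALSE) {
  stopifnot(inherits(meta, "logseries_meta"),
            inherits(config, "lattice_config"))
  cum <- cumsum(meta$abundance / meta$N)
  nt <- neighbor_table(config$rows, config$cols, config$edge)
  if (!is.null(init)) init <- init - 1L
  res <- .sim_lattice_engine(cum, nt$nb, nt$cnt, config$J,
                             config$m_adj, config$m_meta,
                             config$generations * config$J, init)
  coords <- data.frame(
    row = rep(seq_len(config$rows), config$cols),
    col = rep(seq_len(config$cols), each = config$rows))
  out <- as_community_matrix(res$counts, meta, coords)
  attr(out, "sources") <- res$sources
  if (keep_state) attr(out, "state") <- res$state + 1L
  out
}

#' Burn-in diagnostics for the neutral simulators
#'
#' Runs a simulation in chunks and records, after every `snapshot_every`
#' generations, the pooled species richness and the mean within-plot
#' probability of conspecific identity. Used to verify that the default run
#' length reaches a stationary plateau.
#'
#' @param meta a [logseries_metacommunity()] object.
#' @param config an [implicit_config()] or [lattice_config()]; its
#'   `generations` field sets the total trace length.
#' @param snapshot_every snapshot interval in generations (>= 1).
#' @return A data frame with columns `generation`, `events`, `richness`,
#'   `mean_identity`.
#' @export
stationarity_trace <- function(meta, config, snapshot_every = 10) {
  stopifnot(snapshot_every >= 1)
  total <- config$generations
  steps <- c(0, seq(snapshot_every, total, by = snapshot_every))
  if (steps[length(steps)] < total) steps <- c(steps, total)
  state <- NULL
  out <- data.frame()
  n_plots <- if (inherits(config, "lattice_config"))
    config$rows * config$cols else config$n_plots
  for (i in seq_along(steps)) {
    gen <- if (i == 1) 0 else steps[i] - steps[i - 1]
    cfg <- config
    cfg$generations <- gen
    mat <- if (inherits(config, "lattice_config"))
      run_lattice(meta, cfg, init = state, keep_state = TRUE)
    else run_implicit(meta, cfg, init = state, keep_state = TRUE)
    state <- attr(mat, "state")
    out <- rbind(out, data.frame(
      generation = steps[i],
      events = steps[i] * config$J * n_plots,
      richness = sum(colSums(mat) > 0),
      mean_identity = mean(apply(mat, 1, simpson_identity))))
  }
  out
}
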