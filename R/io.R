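#' Write / read a metacommunity as CSV
#'
#' Two-column CSV (`rank,abundance`) with a commented key-value header block
#' (`# N=`, `# S=`, `# alpha=`, `# x=`) so a file round-trips losslessly.
#'
#' @param meta a [logseries_metacommunity()] object.
#' @param path file path.
#' @return `write_metacommunity` returns `path` invisibly;
#'   `read_metacommunity` returns a `logseries_meta` object.
#' @export
write_metacommunity <- function(meta, path) {
  stopifnot(inherits(meta, "logseries_meta"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# N=%.0f", meta$N),
               sprintf("# S=%d", meta$S),
               sprintf("# alpha=%.17g", meta$alpha),
               sprintf("# x=%.17g", meta$x),
               "rank,abundance"), con)
  writeLines(sprintf("%d,%.0f", seq_len(meta$S), meta$abundance), con)
  invisible(path)
}

#' @rdname write_metacommunity
#' @export
read_metacommunity <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", hdr), "="))
  get <- function(k) as.numeric(kv[kv[, 1] == k, 2])
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  abund <- as.numeric(body$abundance[order(body$rank)])
  structure(list(N = get("N"), S = as.integer(get("S")),
                 alpha = get("alpha"), x = get("x"),
                 abundance = abund,
                 species = sprintf("sp%06d", seq_along(abund))),
            class = "logseries_meta")
}

#' Write a community matrix as CSV
#'
#' Wide dialect: one row per plot, one column per species, integer cells, a
#' leading `plot` column and (when present) `row`/`col` lattice coordinates.
#' Long dialect: columns `plot,species,count` with zero cells omitted.
#'
#' @param mat a `community_matrix` (or plain plots x species matrix).
#' @param path file path.
#' @param dialect `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(mat, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  coords <- attr(mat, "coords")
  m <- as.matrix(mat)
  plots <- rownames(m)
  if (is.null(plots)) plots <- sprintf("plot%03d", seq_len(nrow(m)))
  if (dialect == "wide") {
    df <- data.frame(plot = plots, check.names = FALSE)
    if (!is.null(coords)) { df$row <- coords$row; df$col <- coords$col }
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    idx <- which(m > 0, arr.ind = TRUE)
    df <- data.frame(plot = plots[idx[, 1]],
                     species = colnames(m)[idx[, 2]],
                     count = m[idx])
    df <- df[order(df$plot, df$species), ]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a community matrix from CSV
#'
#' Accepts both dialects written by [write_community_matrix()]; the dialect
#' is detected from the header unless given. Species columns whose total is
#' zero are dropped with a warning; plot order is preserved.
#'
#' @param path file path.
#' @param dialect `"auto"` (default), `"wide"` or `"long"`.
#' @return A `community_matrix` (integer counts; `coords` attribute if the
#'   file carries `row`/`col` columns).
#' @export
read_community_matrix <- function(path, dialect = c("auto", "wide", "long")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE)
  if (dialect == "auto")
    dialect <- if (all(c("plot", "species", "count") %in% names(df)))
      "long" else "wide"
  if (dialect == "long") {
    plots <- unique(df$plot)
    species <- sort(unique(df$species))
    m <- matrix(0, length(plots), length(species),
                dimnames = list(plots, species))
    m[cbind(match(df$plot, plots), match(df$species, species))] <- df$count
    coords <- NULL
  } else {
    plots <- df$plot
    coords <- if (all(c("row", "col") %in% names(df)))
      data.frame(row = df$row, col = df$col) else NULL
    keep <- setdiff(names(df), c("plot", "row", "col"))
    m <- as.matrix(df[, keep, drop = FALSE])
    rownames(m) <- plots
  }
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-integer count at plot '", rownames(m)[bad[1, 1]],
         "', species '", colnames(m)[bad[1, 2]], "'")
  zero <- colSums(m) == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " species column(s) with zero total")
    m <- m[, !zero, drop = FALSE]
  }
  storage.mode(m) <- "integer"
  if (!is.null(coords)) attr(m, "coords") <- coords
  class(m) <- c("community_matrix", class(m))
  m
}

#' Deterministic small fixtures for tests and examples
#'
#' Builds, under a fixed seed, a tiny metacommunity (N = 10,000, S = 50), a
#' spatially implicit community matrix (10 plots, J = 100, m = 0.2) and a
#' lattice community matrix (4 x 4 plots, J = 50, m_adj = m_meta = 0.1).
#'
#' @param seed integer seed.
#' @return List with elements `meta`, `implicit`, `lattice`.
#' @export
make_fixtures <- function(seed = 1) {
  meta <- logseries_metacommunity(1e4, S = 50)
  set.seed(seed)
  implicit <- run_implicit(meta, implicit_config(10, 100, 0.2, 50))
  lattice <- run_lattice(meta, lattice_config(4, 4, 50, 0.1, 0.1, 50))
  list(meta = meta, implicit = implicit, lattice = lattice)
}
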