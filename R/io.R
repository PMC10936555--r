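#' Read a set of Newick trees, one per line
#'
#' @param path file with one Newick string per nonempty line.
#' @return list of `phylo` trees, in file order.
#' @export
read_newick_set <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("no trees found in ", path)
  trees <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    tr <- tryCatch(
      suppressWarnings(ape::read.tree(text = lines[keep[j]])),
      error = function(e) NULL
    )
    if (is.null(tr) || !inherits(tr, "phylo") || is.null(tr$edge) ||
        !length(tr$tip.label)) {
      stop("malformed Newick at line ", keep[j], " of ", path)
    }
    tr$tip.label <- trimws(tr$tip.label)
    trees[[j]] <- tr
  }
  trees
}

#' @rdname read_newick_set
#' @param trees list of `phylo` trees to write.
#' @export
write_newick_set <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, ape::write.tree, character(1L)), path)
  invisible(path)
}

#' Read a karyotype tip table
#'
#' CSV with mandatory columns `species` and `counts` (semicolon-separated
#' positive integers) and optional `p_wingless`, `family`, `suborder`.
#' Duplicate species rows are merged by uniting their count sets (multiple
#' reported counts per species are all retained and later resampled per
#' model fit).
#'
#' @param path CSV path.
#' @return a data.frame of class `karyotype_table` with a list-column
#'   `counts` of integer vectors.
#' @export
read_tip_table <- function(path) {
  if (!file.exists(path)) stop("tip table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("species", "counts")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("tip table missing column(s): ", paste(miss, collapse = ", "))
  parse_counts <- function(sp, txt) {
    parts <- trimws(strsplit(txt, ";", fixed = TRUE)[[1L]])
    parts <- parts[nzchar(parts)]
    if (!length(parts) || !all(grepl("^[0-9]+$", parts))) {
      stop("non-integer count '", txt, "' for species '", sp, "'")
    }
    v <- as.integer(parts)
    if (any(v < 1L)) stop("count < 1 for species '", sp, "'")
    sort(unique(v))
  }
  counts <- mapply(parse_counts, df$species, df$counts, SIMPLIFY = FALSE)
  p <- if ("p_wingless" %in% names(df)) {
    pv <- suppressWarnings(as.numeric(df$p_wingless))
    bad <- !is.na(df$p_wingless) & nzchar(df$p_wingless) &
      (is.na(pv) | pv < 0 | pv > 1)
    if (any(bad)) {
      stop("p_wingless outside [0, 1] for species: ",
           paste(df$species[bad], collapse = ", "))
    }
    pv
  } else {
    rep(NA_real_, nrow(df))
  }
  out <- data.frame(species = df$species, stringsAsFactors = FALSE)
  out$counts <- counts
  out$p_wingless <- p
  for (extra in intersect(c("family", "suborder", "genus"), names(df))) {
    out[[extra]] <- df[[extra]]
  }
  if (anyDuplicated(out$species)) {
    merged <- lapply(split(seq_len(nrow(out)), out$species), function(rows) {
      first <- out[rows[1L], , drop = FALSE]
      first$counts <- list(sort(unique(unlist(out$counts[rows]))))
      pvals <- unique(stats::na.omit(out$p_wingless[rows]))
      if (length(pvals) > 1L) {
        warning("conflicting p_wingless for species '", first$species,
                "'; keeping the first")
      }
      first$p_wingless <- if (length(pvals)) pvals[1L] else NA_real_
      first
    })
    out <- do.call(rbind, merged[unique(out$species)])
    rownames(out) <- NULL
  }
  class(out) <- c("karyotype_table", class(out))
  out
}

#' Convert a karyotype table to tip data
#'
#' @param table a `karyotype_table` from [read_tip_table()].
#' @return list of [tip_data()] objects.
#' @export
as_tip_data <- function(table) {
  lapply(seq_len(nrow(table)), function(i) {
    tip_data(table$species[i], table$counts[[i]], table$p_wingless[i])
  })
}

#' Summarise chromosome-count records
#'
#' Species with several retained counts contribute one record per value, so
#' ranges, means and modes read over records (as database summaries do).
#' The reported `mean` comes with the standard error of the mean
#' (`se = sd / sqrt(n)`, `NA` for a single record); `mode` is the most
#' frequent count (smallest on ties) and `mode_share` its fraction of
#' records.
#'
#' @param table a `karyotype_table`.
#' @param group_by optional column of `table` (e.g. `"suborder"`) to
#'   summarise within; `NULL` summarises everything as one group.
#' @return data.frame with one row per group, ordered by group label:
#'   `group`, `n`, `min`, `max`, `mean`, `se`, `mode`, `mode_share`.
#' @export
summarize_counts <- function(table, group_by = NULL) {
  stopifnot(nrow(table) > 0L)
  if (!is.null(group_by) && !group_by %in% names(table)) {
    stop("unknown group column: ", group_by)
  }
  reps <- vapply(table$counts, length, integer(1L))
  records <- data.frame(
    count = unlist(table$counts),
    group = if (is.null(group_by)) "all" else rep(table[[group_by]], reps),
    stringsAsFactors = FALSE
  )
  one <- function(x) {
    tab <- table(x)
    mode_ct <- as.integer(names(tab)[which.max(tab)])  # which.max: first = smallest
    data.frame(
      n = length(x), min = min(x), max = max(x), mean = mean(x),
      se = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_,
      mode = mode_ct, mode_share = max(tab) / length(x)
    )
  }
  groups <- sort(unique(records$group))
  out <- do.call(rbind, lapply(groups, function(g) {
    cbind(data.frame(group = g, stringsAsFactors = FALSE),
          one(records$count[records$group == g]))
  }))
  rownames(out) <- NULL
  out
}

#' Load a synthetic study fixture from disk
#'
#' Reads the `trees.nwk` / `tips.csv` / `truth.json` layout written by
#' [make_synthetic_study()].
#'
#' @param dir fixture directory.
#' @return list with `trees`, `tips` (list of [tip_data()]), `tip_table`,
#'   `truth`.
#' @export
read_study <- function(dir) {
  trees <- read_newick_set(file.path(dir, "trees.nwk"))
  tab <- read_tip_table(file.path(dir, "tips.csv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  list(trees = trees, tips = as_tip_data(tab), tip_table = tab, truth = truth)
}
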