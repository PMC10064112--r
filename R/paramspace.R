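## Parameter-space curation: the pipeline that turns a raw species-parameter
## table (one row per species, AmP-style columns) into a small set of
## biologically plausible (assimilation, conductance) combinations.

require_columns <- function(table, cols, what) {
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0L)
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(table)
}

#' Filter a species table by model type, lifespan and data completeness
#'
#' Keeps rows whose model label matches, whose lifespan is strictly below
#' `max_lifespan` and whose data-completeness score is at least
#' `min_completeness` (the inequality senses follow the curation protocol:
#' lifespan `< 100` years, completeness `>= 2.5`).
#'
#' @param table data frame with columns `model_type`, `lifespan_y`,
#'   `completeness` (other columns are passed through).
#' @param model_label model-type label to keep (default `"std"`).
#' @param max_lifespan exclusive upper bound on lifespan in years.
#' @param min_completeness inclusive lower bound on the 0-10 completeness
#'   score.
#' @return The filtered table.
#' @export
filter_species <- function(table, model_label = "std", max_lifespan = 100,
                           min_completeness = 2.5) {
  require_columns(table, c("model_type", "lifespan_y", "completeness"),
                  "filter_species")
  keep <- table$model_type == model_label &
    table$lifespan_y < max_lifespan &
    table$completeness >= min_completeness
  table[which(keep), , drop = FALSE]
}

#' Remove rows outside interquartile-range fences
#'
#' For each listed column, computes the quartiles (linear-interpolation
#' quantiles, `type = 7` by default; the fence membership of borderline
#' values depends on this convention, hence it is configurable) and removes
#' every row with any listed value below `Q1 - k * IQR` or above
#' `Q3 + k * IQR`. Fences are computed once on the input table, not
#' re-estimated after removals.
#'
#' @param table data frame.
#' @param columns numeric columns to fence.
#' @param k fence multiplier (default 1.5).
#' @param quantile_type passed to [stats::quantile()].
#' @return The filtered table. With fewer than 4 rows the fences are
#'   undefined and the table is returned unchanged with a warning.
#' @export
iqr_outlier_filter <- function(table,
                               columns = c("p_Am_max", "v_dot", "kappa", "p_M_vol"),
                               k = 1.5, quantile_type = 7) {
  require_columns(table, columns, "iqr_outlier_filter")
  if (k <= 0) stop("'k' must be positive", call. = FALSE)
  if (nrow(table) < 4L) {
    warning("fewer than 4 rows: interquartile fences undefined, table returned unchanged")
    return(table)
  }
  keep <- rep(TRUE, nrow(table))
  for (cl in columns) {
    x <- table[[cl]]
    q <- stats::quantile(x, c(0.25, 0.75), type = quantile_type, names = FALSE)
    iqr <- q[2L] - q[1L]
    keep <- keep & x >= q[1L] - k * iqr & x <= q[2L] + k * iqr
  }
  table[which(keep), , drop = FALSE]
}

bin_index <- function(x, lo, hi, n_bins) {
  if (hi <= lo) return(rep(1L, length(x)))
  w <- (hi - lo) / n_bins
  pmin(pmax(floor((x - lo) / w) + 1L, 1L), n_bins)
}

bin_midpoint <- function(idx, lo, hi, n_bins) {
  if (hi <= lo) return(rep(lo, length(idx)))
  w <- (hi - lo) / n_bins
  lo + (idx - 0.5) * w
}

#' Discretize the joint (assimilation, conductance) distribution
#'
#' Partitions the observed range of each of the two parameters into
#' `n_bins` equal-width intervals (the last interval is right-closed) and
#' maps every species to its interval in each dimension. Each interval is
#' represented by its midpoint (the mean of its endpoints); alternatively
#' the mean of its member values can be used. Returns the occupied joint
#' combinations with their occurrence frequencies, which sum to the row
#' count.
#'
#' @param table data frame with the two parameter columns.
#' @param n_bins number of intervals per dimension (default 5).
#' @param cols named character vector mapping `pAm` and `v` to column names
#'   in `table`.
#' @param representative `"midpoint"` (default) or `"member-mean"`.
#' @return Data frame of class `deb_combos` with columns `pAm_bin`,
#'   `pAm_value`, `v_bin`, `v_value`, `frequency`; the attribute `n_bins`
#'   records the grid.
#' @export
joint_discretize <- function(table, n_bins = 5,
                             cols = c(pAm = "p_Am_max", v = "v_dot"),
                             representative = c("midpoint", "member-mean")) {
  representative <- match.arg(representative)
  require_columns(table, unname(cols), "joint_discretize")
  if (nrow(table) < 1L) stop("'table' must contain at least one row", call. = FALSE)
  if (!is.numeric(n_bins) || n_bins < 1) stop("'n_bins' must be >= 1", call. = FALSE)
  x <- table[[cols[["pAm"]]]]; y <- table[[cols[["v"]]]]
  rx <- range(x); ry <- range(y)
  bx <- bin_index(x, rx[1L], rx[2L], n_bins)
  by <- bin_index(y, ry[1L], ry[2L], n_bins)
  key <- paste(bx, by)
  agg <- data.frame(pAm_bin = bx, v_bin = by)
  tab <- table(key)
  first <- !duplicated(key)
  combos <- data.frame(pAm_bin = bx[first], v_bin = by[first],
                       frequency = as.integer(tab[key[first]]))
  if (representative == "midpoint") {
    combos$pAm_value <- bin_midpoint(combos$pAm_bin, rx[1L], rx[2L], n_bins)
    combos$v_value <- bin_midpoint(combos$v_bin, ry[1L], ry[2L], n_bins)
  } else {
    combos$pAm_value <- vapply(seq_len(nrow(combos)), function(i)
      mean(x[bx == combos$pAm_bin[i]]), numeric(1))
    combos$v_value <- vapply(seq_len(nrow(combos)), function(i)
      mean(y[by == combos$v_bin[i]]), numeric(1))
  }
  combos <- combos[order(combos$pAm_bin, combos$v_bin),
                   c("pAm_bin", "pAm_value", "v_bin", "v_value", "frequency")]
  rownames(combos) <- NULL
  attr(combos, "n_bins") <- n_bins
  class(combos) <- c("deb_combos", "data.frame")
  combos
}

#' Prune discretized parameter combinations
#'
#' Applies the final curation steps to the discretized joint distribution:
#' drop combinations observed fewer than `min_frequency` times, keep one
#' entry per unique (assimilation bin, conductance bin) pair, and finally
#' remove edge outliers - retained pairs that have no other retained pair
#' among their 8 neighbours on the discrete grid. Edge removal is a single
#' simultaneous pass over the retained set.
#'
#' @param combos a [joint_discretize()] result.
#' @param min_frequency minimum occurrence frequency to retain (default 2).
#' @param drop_edge_outliers whether to apply the isolation rule.
#' @return The pruned combos table.
#' @export
prune_combos <- function(combos, min_frequency = 2, drop_edge_outliers = TRUE) {
  require_columns(combos, c("pAm_bin", "v_bin", "frequency"), "prune_combos")
  combos <- combos[combos$frequency >= min_frequency, , drop = FALSE]
  combos <- combos[!duplicated(combos[, c("pAm_bin", "v_bin")]), , drop = FALSE]
  if (drop_edge_outliers && nrow(combos) > 0L) {
    has_neighbour <- vapply(seq_len(nrow(combos)), function(i) {
      dx <- abs(combos$pAm_bin - combos$pAm_bin[i])
      dy <- abs(combos$v_bin - combos$v_bin[i])
      any(dx <= 1 & dy <= 1 & (dx + dy > 0))
    }, logical(1))
    combos <- combos[has_neighbour, , drop = FALSE]
  }
  rownames(combos) <- NULL
  combos
}

#' Query species inside a parameter box
#'
#' Keeps rows whose listed parameters all lie within closed intervals. The
#' allocation fraction `kappa` is deliberately not part of the default box:
#' species collections are biased towards high values of `kappa`, so it is
#' left unconstrained when checking whether real species fall inside the
#' swept parameter space.
#'
#' @param table data frame.
#' @param box named list of `c(lower, upper)` closed intervals per column;
#'   the default is the validation box used for the sweep
#'   (`v_dot` in \[0.15, 0.55\], `p_Am_max` in \[1500, 9500\], `p_M_vol`
#'   in \[1600, 2000\]).
#' @return Rows of `table` inside the box.
#' @export
validation_box_query <- function(table,
                                 box = list(v_dot = c(0.15, 0.55),
                                            p_Am_max = c(1500, 9500),
                                            p_M_vol = c(1600, 2000))) {
  require_columns(table, names(box), "validation_box_query")
  keep <- rep(TRUE, nrow(table))
  for (nm in names(box)) {
    iv <- box[[nm]]
    if (length(iv) != 2L || iv[1L] > iv[2L])
      stop("box interval for '", nm, "' must be c(lower, upper)", call. = FALSE)
    keep <- keep & table[[nm]] >= iv[1L] & table[[nm]] <= iv[2L]
  }
  table[which(keep), , drop = FALSE]
}

#' Coefficient of variation
#'
#' `c_v = sd(x) / mean(x)` with the sample (n - 1) standard deviation.
#'
#' @param values numeric vector with at least 2 values and nonzero mean.
#' @return The coefficient of variation.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("at least two values are required", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("coefficient of variation is undefined for zero mean", call. = FALSE)
  stats::sd(values) / m
}

#' Run the full curation pipeline
#'
#' Convenience composition: [filter_species()] then [iqr_outlier_filter()]
#' then [joint_discretize()] then [prune_combos()]. Every stage is
#' deterministic, so a fixed input table always yields an identical combo
#' set.
#'
#' @param table a species table.
#' @param model_label,max_lifespan,min_completeness see [filter_species()].
#' @param iqr_columns,iqr_k see [iqr_outlier_filter()].
#' @param n_bins,representative see [joint_discretize()].
#' @param min_frequency,drop_edge_outliers see [prune_combos()].
#' @return The pruned combos table.
#' @export
curate_parameter_space <- function(table, model_label = "std",
                                   max_lifespan = 100, min_completeness = 2.5,
                                   iqr_columns = c("p_Am_max", "v_dot", "kappa", "p_M_vol"),
                                   iqr_k = 1.5, n_bins = 5,
                                   representative = "midpoint",
                                   min_frequency = 2,
                                   drop_edge_outliers = TRUE) {
  kept <- filter_species(table, model_label, max_lifespan, min_completeness)
  kept <- iqr_outlier_filter(kept, iqr_columns, iqr_k)
  combos <- joint_discretize(kept, n_bins, representative = representative)
  prune_combos(combos, min_frequency, drop_edge_outliers)
}

#' Read or write a species table
#'
#' CSV with a mandatory header. `column_map` renames file columns to the
#' canonical names (`species_id`, `model_type`, `lifespan_y`,
#' `completeness`, `p_Am_max`, `v_dot`, `kappa`, `p_M_vol`) on read.
#'
#' @param path file path.
#' @param column_map optional named character vector `c(canonical = "file_name")`.
#' @return For `read_species_table`, the table as a data frame.
#' @export
read_species_table <- function(path, column_map = NULL) {
  table <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      j <- match(column_map[[canonical]], names(table))
      if (is.na(j)) stop("column '", column_map[[canonical]], "' not found in ", path,
                         call. = FALSE)
      names(table)[j] <- canonical
    }
  }
  table
}

#' @rdname read_species_table
#' @param table a species table.
#' @export
write_species_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
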