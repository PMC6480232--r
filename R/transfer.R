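#' Per-source unit-emission couplings for one hour
#'
#' Runs the dispersion kernels with unit emissions for every source at every
#' receptor for a single (non-calm) met hour.
#'
#' @param sources list of [line_source()] / [area_source()] objects.
#' @param rec receptor data frame (`id`, `x`, `y`, `z`).
#' @param met one met record.
#' @param params [dispersion_params()].
#' @return numeric matrix receptors x sources of couplings (s/m^3 per unit
#'   total source emission rate), dimnames set to receptor and source ids.
#' @export
hourly_unit_couplings <- function(sources, rec, met,
                                  params = dispersion_params()) {
  M <- vapply(sources, function(s) {
    if (s$type == "line") .line_coupling_multi(s, rec$x, rec$y, rec$z, met, params)
    else .area_coupling_multi(s, rec$x, rec$y, rec$z, met, params)
  }, numeric(nrow(rec)))
  M <- matrix(M, nrow = nrow(rec),
              dimnames = list(rec$id, vapply(sources, `[[`, character(1), "id")))
  M
}

#' Build the receptor-by-category transfer matrix
#'
#' For each non-calm hour the unit-emission couplings of all sources are
#' computed, grouped into categories with the allocation weights (a category
#' "unit emission" is split among its member sources), averaged over the
#' period, and converted so that entry `T[i, k]` is the concentration at
#' receptor `i` in ug/m^3 per ton/day emitted by category `k`.
#'
#' @param sources list of source objects.
#' @param rec receptor data frame.
#' @param met a `surface_met` table; calm hours (u* <= `ustar_min`) are
#'   excluded before averaging.
#' @param grouping data frame `id, category, weight` (default
#'   [default_grouping()]: length-proportional allocation).
#' @param params [dispersion_params()].
#' @param ustar_min calm threshold m/s (default 0.1).
#' @param period optional label stored in the result.
#' @return object of class `transfer_matrix`: list with `values`
#'   (receptors x categories matrix), `receptors`, `categories`,
#'   `n_hours_used`, `period`.
#' @export
build_transfer_matrix <- function(sources, rec, met, grouping = NULL,
                                  params = dispersion_params(),
                                  ustar_min = 0.1, period = NA_character_) {
  if (is.null(grouping)) grouping <- default_grouping(sources)
  met_use <- suppressMessages(filter_calm(met, ustar_min))
  n_hours <- nrow(met_use)
  if (n_hours < 1L) {
    stop("build_transfer_matrix: no usable (non-calm) hours in period ", period)
  }
  cats <- .category_levels(grouping$category)
  src_ids <- vapply(sources, `[[`, character(1), "id")
  # receptors x categories weight aggregation matrix: sources x categories
  W <- matrix(0, length(sources), length(cats),
              dimnames = list(src_ids, cats))
  for (r in seq_len(nrow(grouping))) {
    W[grouping$id[r], grouping$category[r]] <- grouping$weight[r]
  }
  acc <- matrix(0, nrow(rec), length(cats))
  for (hh in seq_len(n_hours)) {
    m <- as.list(met_use[hh, ])
    acc <- acc + hourly_unit_couplings(sources, rec, m, params) %*% W
  }
  values <- .coupling_to_ug_per_tpd(acc / n_hours)
  dimnames(values) <- list(rec$id, cats)
  structure(list(values = values, receptors = rec$id, categories = cats,
                 n_hours_used = n_hours, period = period),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("Transfer matrix:", length(x$receptors), "receptors x",
      length(x$categories), "categories (ug/m^3 per ton/day),",
      x$n_hours_used, "hours averaged\n")
  print(round(x$values, 4))
  invisible(x)
}

# coerce transfer_matrix or plain matrix to the numeric matrix of values
.tm_values <- function(T) {
  v <- if (inherits(T, "transfer_matrix")) T$values else as.matrix(T)
  if (is.null(colnames(v))) colnames(v) <- paste0("cat", seq_len(ncol(v)))
  v
}

#' Write / read a transfer matrix as CSV with a metadata sidecar
#'
#' @param tm a `transfer_matrix`.
#' @param path CSV path; a sidecar `<path>.meta.yaml` stores period,
#'   hours used and (optionally) a configuration hash.
#' @param config_md5 optional provenance hash recorded in the sidecar.
#' @export
write_transfer_matrix <- function(tm, path, config_md5 = NULL) {
  df <- data.frame(receptor_id = tm$receptors, tm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(period = tm$period, n_hours_used = tm$n_hours_used,
                        categories = tm$categories, config_md5 = config_md5),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_transfer_matrix
#' @export
read_transfer_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$receptor_id
  structure(list(values = values, receptors = df$receptor_id,
                 categories = colnames(values),
                 n_hours_used = meta$n_hours_used, period = meta$period,
                 config_md5 = meta$config_md5),
            class = "transfer_matrix")
}
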