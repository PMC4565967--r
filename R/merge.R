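#' Merge CEG sets of multiple lncRNAs within one dataset
#'
#' Combines the CEG sets of several lncRNAs from the same dataset by union
#' (coordinated correlation: genes co-expressed with any of the lncRNAs) or
#' intersection (cooperative correlation: genes co-expressed with all of
#' them). An empty intersection is legal and logged, not an error.
#'
#' @param cegs A `coex_result`, a CEG tibble for one dataset, or a named list
#'   of per-lncRNA member vectors.
#' @param mode `"union"` or `"intersection"`.
#' @param lnc_ids Optional subset of lncRNA ids to merge (default: all present;
#'   a requested lncRNA with no CEG rows contributes the empty set).
#' @return Sorted character vector of merged protein-coding gene ids.
#' @export
merge_within_dataset <- function(cegs, mode = c("union", "intersection"),
                                 lnc_ids = NULL) {
  mode <- match.arg(mode)
  if (inherits(cegs, "coex_result")) cegs <- cegs$cegs
  if (is.data.frame(cegs)) {
    if ("dataset_id" %in% names(cegs) && length(unique(cegs$dataset_id)) > 1L) {
      abort(sprintf(
        "merge_within_dataset expects CEGs from a single dataset, found: %s",
        paste(unique(cegs$dataset_id), collapse = ", ")
      ))
    }
    sets <- ceg_members(cegs)
  } else {
    sets <- cegs
  }
  if (!is.null(lnc_ids)) {
    sets <- setNames(
      map(lnc_ids, ~ sets[[.x]] %||% character(0)),
      lnc_ids
    )
  }
  if (length(sets) == 0L) {
    abort("no CEG sets to merge")
  }
  out <- merge_sets(sets, mode)
  if (length(out) == 0L) {
    log_info(sprintf(
      "merge_within_dataset: %s of %d CEG sets is empty", mode, length(sets)
    ))
  }
  out
}

merge_sets <- function(sets, mode) {
  sets <- map(sets, ~ unique(as.character(.x)))
  merged <- switch(mode,
    union = reduce(sets, union),
    intersection = reduce(sets, intersect)
  )
  sort(merged)
}

#' Merge per-dataset CEG sets across datasets
#'
#' Second stage of the two-level merge: the per-dataset merged sets (from
#' [merge_within_dataset()]) are combined across datasets by union or
#' intersection. The two stages are strictly sequential — within each dataset
#' first, then across — because the two orders differ when the modes are
#' mixed.
#'
#' @param per_dataset Named list mapping `dataset_id` to a merged gene-id set.
#' @param mode `"union"` or `"intersection"`.
#' @return A `merged_cegs` object: `members` (sorted gene ids),
#'   `per_dataset_members`, and `across_mode`.
#' @export
merge_across_datasets <- function(per_dataset, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (length(per_dataset) == 0L) {
    abort("per_dataset mapping is empty")
  }
  if (is.null(names(per_dataset)) || any(!nzchar(names(per_dataset)))) {
    abort("per_dataset must be a named list keyed by dataset_id")
  }
  per_dataset <- map(per_dataset, ~ sort(unique(as.character(.x))))
  members <- merge_sets(per_dataset, mode)
  if (length(members) == 0L) {
    log_info(sprintf(
      "merge_across_datasets: %s across %d datasets is empty",
      mode, length(per_dataset)
    ))
  }
  structure(
    list(
      members = members,
      per_dataset_members = per_dataset,
      across_mode = mode
    ),
    class = "merged_cegs"
  )
}

#' @export
print.merged_cegs <- function(x, ...) {
  cat(sprintf(
    "<merged_cegs> %d genes (%s across %d dataset(s): %s)\n",
    length(x$members), x$across_mode, length(x$per_dataset_members),
    paste(names(x$per_dataset_members), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname merge_across_datasets
#' @param x A `merged_cegs`.
#' @param ... Unused.
#' @method tidy merged_cegs
#' @export
tidy.merged_cegs <- function(x, ...) {
  all_genes <- sort(unique(c(x$members, unlist(x$per_dataset_members))))
  out <- tibble(gene_id = all_genes, in_merged = all_genes %in% x$members)
  for (ds in names(x$per_dataset_members)) {
    out[[paste0("in_", ds)]] <- all_genes %in% x$per_dataset_members[[ds]]
  }
  out
}

#' @rdname merge_across_datasets
#' @method glance merged_cegs
#' @export
glance.merged_cegs <- function(x, ...) {
  tibble(
    across_mode = x$across_mode,
    n_datasets = length(x$per_dataset_members),
    n_members = length(x$members)
  )
}

#' Write a merged CEG set with per-dataset presence indicators
#'
#' @param x A `merged_cegs`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_merged_cegs <- function(x, path) {
  stopifnot(inherits(x, "merged_cegs"))
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
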