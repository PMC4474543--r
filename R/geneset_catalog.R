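#' Canonical analysis-set names
#' @keywords internal
canonical_set_names <- function() c("TSG", "OCG", "Target", "Essential")

#' Assemble the gene-set catalog over a network's node universe
#'
#' Maps each named gene set onto the network (intersection with the node
#' universe), derives the complement set `Other` — every network node not in
#' any named set — and records all pairwise overlaps among the named sets.
#' The named sets may overlap each other (e.g. drug targets that are also
#' oncogenes); `Other` is disjoint from all of them by construction. A gene
#' belonging to two sets contributes to both sets' distributions in every
#' downstream statistic.
#'
#' @param network an `igraph` interaction network.
#' @param named_sets named list of symbol vectors. Must contain the four
#'   canonical names `TSG`, `OCG`, `Target`, `Essential`; extra custom sets
#'   are allowed.
#' @param quiet suppress unmapped-symbol messages.
#' @return a `gene_catalog` with elements `sets` (input sets), `mapped`
#'   (intersections with the universe, including `Other`), `universe`,
#'   `unmapped`, and `overlaps` (tibble).
#' @export
build_catalog <- function(network, named_sets, quiet = FALSE) {
  stopifnot(igraph::is_igraph(network))
  missing_sets <- setdiff(canonical_set_names(), names(named_sets))
  if (length(missing_sets) > 0L) {
    oncotopo_abort(sprintf(
      "named_sets must include the canonical sets: missing %s",
      paste(missing_sets, collapse = ", ")
    ), "catalog")
  }
  universe <- igraph::V(network)$name
  named_sets <- lapply(named_sets, function(s) unique(stringr::str_trim(s)))
  mapped <- lapply(named_sets, intersect, y = universe)
  unmapped <- purrr::map2(named_sets, mapped, setdiff)
  empty <- names(mapped)[lengths(mapped) == 0L]
  if (length(empty) > 0L) {
    oncotopo_abort(sprintf(
      "gene set(s) map to zero network nodes: %s",
      paste(empty, collapse = ", ")
    ), "catalog")
  }
  if (!quiet) {
    for (nm in names(unmapped)) {
      if (length(unmapped[[nm]]) > 0L) {
        rlang::inform(sprintf(
          "build_catalog: %d of %d '%s' symbols not in the network (%s)",
          length(unmapped[[nm]]), length(named_sets[[nm]]), nm,
          paste(head(unmapped[[nm]], 5L), collapse = ", ")
        ))
      }
    }
  }
  other <- setdiff(universe, unlist(mapped, use.names = FALSE))
  mapped$Other <- other

  cat <- structure(
    list(
      sets = named_sets,
      mapped = mapped,
      universe = universe,
      unmapped = unmapped,
      overlaps = NULL
    ),
    class = "gene_catalog"
  )
  cat$overlaps <- overlap_report(cat)
  cat
}

#' Pairwise overlaps among mapped gene sets
#'
#' @param catalog a `gene_catalog`.
#' @return tibble with one row per unordered set pair with a nonzero
#'   intersection: `set_a`, `set_b`, `n_shared`, `symbols` (list column).
#' @export
overlap_report <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  nms <- setdiff(names(catalog$mapped), "Other")
  if (length(nms) < 2L) {
    return(tibble(set_a = character(), set_b = character(),
                  n_shared = integer(), symbols = list()))
  }
  pairs <- utils::combn(sort(nms), 2L, simplify = FALSE)
  rows <- purrr::map(pairs, function(p) {
    shared <- sort(intersect(catalog$mapped[[p[[1]]]], catalog$mapped[[p[[2]]]]))
    tibble(set_a = p[[1]], set_b = p[[2]], n_shared = length(shared), symbols = list(shared))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::filter(out, .data$n_shared > 0L)
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> universe of %d network nodes\n", length(x$universe)))
  for (nm in names(x$mapped)) {
    input_n <- if (nm %in% names(x$sets)) sprintf(" (of %d input)", length(x$sets[[nm]])) else ""
    cat(sprintf("  %-10s %5d mapped%s\n", nm, length(x$mapped[[nm]]), input_n))
  }
  if (!is.null(x$overlaps) && nrow(x$overlaps) > 0L) {
    cat(sprintf("  %d overlapping set pair(s)\n", nrow(x$overlaps)))
  }
  invisible(x)
}

#' Catalog membership as a long tibble
#'
#' @param x a `gene_catalog`.
#' @param ... unused.
#' @return tibble with columns `set` and `gene`, one row per mapped
#'   membership (genes in several sets appear once per set).
#' @method tidy gene_catalog
#' @export
tidy.gene_catalog <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$mapped, function(genes, nm) {
    tibble(set = nm, gene = genes)
  }))
}

#' One-row catalog summary
#'
#' @param x a `gene_catalog`.
#' @param ... unused.
#' @return tibble with universe size, per-set mapped sizes and the number of
#'   overlapping pairs.
#' @method glance gene_catalog
#' @export
glance.gene_catalog <- function(x, ...) {
  sizes <- lengths(x$mapped)
  dplyr::bind_cols(
    tibble(n_universe = length(x$universe)),
    as_tibble(as.list(setNames(as.integer(sizes), paste0("n_", tolower(names(sizes)))))),
    tibble(n_overlap_pairs = nrow(x$overlaps))
  )
}

#' Serialize a catalog: GMT of mapped sets plus a JSON size/overlap summary
#'
#' @param catalog a `gene_catalog`.
#' @param gmt_path output GMT file of the mapped sets (including `Other`).
#' @param json_path optional JSON summary of sizes and overlaps.
#' @export
write_catalog <- function(catalog, gmt_path, json_path = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"))
  write_gmt(catalog$mapped, gmt_path, description = "mapped")
  if (!is.null(json_path)) {
    summary <- list(
      universe = length(catalog$universe),
      mapped_sizes = lapply(catalog$mapped, length),
      unmapped_sizes = lapply(catalog$unmapped, length),
      overlaps = lapply(seq_len(nrow(catalog$overlaps)), function(i) {
        list(
          set_a = catalog$overlaps$set_a[[i]],
          set_b = catalog$overlaps$set_b[[i]],
          n_shared = catalog$overlaps$n_shared[[i]],
          symbols = catalog$overlaps$symbols[[i]]
        )
      })
    )
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(gmt_path)
}
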