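#' Build an interaction network from endpoint vectors
#'
#' Core constructor behind all network readers. Endpoints are trimmed,
#' self-interactions and redundant (duplicate, order-insensitive) pairs are
#' culled with a logged count, and the result is a simple undirected
#' [igraph][igraph::aaa-igraph-package] graph whose vertex names are gene
#' symbols.
#'
#' @param from,to character vectors of interaction endpoints (gene symbols).
#' @param extra_nodes optional symbols to include as (possibly isolated)
#'   vertices.
#' @param quiet suppress the dropped-row message.
#' @return an undirected simple `igraph` object.
#' @export
as_interaction_network <- function(from, to, extra_nodes = character(), quiet = FALSE) {
  stopifnot(length(from) == length(to))
  from <- stringr::str_trim(as.character(from))
  to <- stringr::str_trim(as.character(to))
  ok <- !is.na(from) & !is.na(to) & from != "" & to != ""
  from <- from[ok]
  to <- to[ok]

  self <- from == to
  n_self <- sum(self)
  from2 <- from[!self]
  to2 <- to[!self]

  a <- pmin(from2, to2)
  b <- pmax(from2, to2)
  dup <- duplicated(paste(a, b, sep = "\r"))
  n_dup <- sum(dup)

  edges <- tibble(from = a[!dup], to = b[!dup])
  nodes <- unique(c(edges$from, edges$to, stringr::str_trim(extra_nodes)))
  nodes <- nodes[nodes != ""]
  if (nrow(edges) == 0L) {
    oncotopo_abort("empty network: no interactions left after parsing", "empty_network")
  }
  if (!quiet && (n_self > 0L || n_dup > 0L)) {
    rlang::inform(sprintf(
      "as_interaction_network: dropped %d self-interaction(s) and %d duplicate row(s)",
      n_self, n_dup
    ))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  igraph::graph_attr(g, "n_dropped_self") <- n_self
  igraph::graph_attr(g, "n_dropped_duplicate") <- n_dup
  g
}

#' Read a protein-protein interaction network
#'
#' Supports plain two-column edge-list TSV (optional header), PSI-MI TAB 2.5
#' ("mitab") and Cytoscape SIF. Symbols are matched exactly after whitespace
#' trimming; no alias or identifier mapping is attempted. Self-interactions
#' and redundant connections are culled (with a logged count), mirroring
#' standard PPI preprocessing.
#'
#' @param path file to read.
#' @param format `"tsv"`, `"mitab"` or `"sif"`.
#' @param header for `"tsv"`: `TRUE`, `FALSE`, or `"auto"` (first line is
#'   treated as a header when it looks like column names).
#' @param mitab_id_cols,mitab_alias_cols 1-based column indices of the two
#'   interactor ID columns and the two alias columns. Gene-symbol-typed
#'   aliases (`...(gene name)`) are preferred; otherwise the interactor ID is
#'   used verbatim (database prefix stripped).
#' @param quiet suppress dropped-row messages.
#' @return an undirected simple `igraph` network.
#' @export
read_interactions <- function(path,
                              format = c("tsv", "mitab", "sif"),
                              header = "auto",
                              mitab_id_cols = c(1L, 2L),
                              mitab_alias_cols = c(5L, 6L),
                              quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    oncotopo_abort(sprintf("cannot read interaction file: '%s' does not exist", path), "io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]

  ends <- switch(format,
    tsv = parse_edge_tsv(lines, header),
    mitab = parse_mitab(lines, mitab_id_cols, mitab_alias_cols),
    sif = parse_sif(lines)
  )
  as_interaction_network(ends$from, ends$to, extra_nodes = ends$extra %||% character(), quiet = quiet)
}

parse_edge_tsv <- function(lines, header) {
  if (length(lines) == 0L) {
    oncotopo_abort("empty network: file has no rows", "empty_network")
  }
  first <- tolower(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]])
  looks_header <- any(first %in% c(
    "from", "to", "source", "target", "gene_a", "gene_b", "genea", "geneb",
    "symbol_a", "symbol_b", "node1", "node2", "interactor_a", "interactor_b"
  ))
  drop_first <- isTRUE(header) || (identical(header, "auto") && looks_header)
  body <- if (drop_first) lines[-1] else lines
  offset <- if (drop_first) 1L else 0L
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    oncotopo_abort(sprintf(
      "malformed edge-list row at line %d: expected at least 2 tab-separated fields",
      bad[[1]] + offset
    ), "parse")
  }
  list(
    from = vapply(fields, `[[`, "", 1L),
    to = vapply(fields, `[[`, "", 2L)
  )
}

# Pull a gene-symbol-typed alias like "uniprotkb:TP53(gene name)" out of a
# pipe-separated MITAB alias field; fall back to the ID column verbatim with
# its database prefix stripped.
mitab_symbol <- function(alias_field, id_field) {
  hit <- regmatches(
    alias_field,
    regexpr("[^|:]+(?=\\(gene name\\))", alias_field, perl = TRUE)
  )
  if (length(hit) == 1L && nzchar(hit)) {
    return(stringr::str_trim(hit))
  }
  stringr::str_trim(sub("^[^:]*:", "", id_field))
}

parse_mitab <- function(lines, id_cols, alias_cols) {
  if (length(lines) > 0L && startsWith(lines[[1]], "#")) {
    lines <- lines[-1]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(id_cols, alias_cols)
  bad <- which(vapply(fields, length, 1L) < max(id_cols))
  if (length(bad) > 0L) {
    oncotopo_abort(sprintf("malformed MITAB row at line %d", bad[[1]]), "parse")
  }
  get_col <- function(f, i) if (length(f) >= i) f[[i]] else ""
  list(
    from = vapply(fields, function(f) mitab_symbol(get_col(f, alias_cols[[1]]), f[[id_cols[[1]]]]), ""),
    to = vapply(fields, function(f) mitab_symbol(get_col(f, alias_cols[[2]]), f[[id_cols[[2]]]]), "")
  )
}

parse_sif <- function(lines) {
  fields <- strsplit(lines, "[\t ]+")
  from <- character()
  to <- character()
  extra <- character()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    f <- f[nzchar(f)]
    if (length(f) == 1L) {
      extra <- c(extra, f)
    } else if (length(f) >= 3L) {
      from <- c(from, rep(f[[1]], length(f) - 2L))
      to <- c(to, f[3:length(f)])
    } else {
      oncotopo_abort(sprintf("malformed SIF row at line %d: 2 fields (need 1 or >= 3)", i), "parse")
    }
  }
  list(from = from, to = to, extra = extra)
}

#' Write a network as a two-column edge-list TSV
#'
#' @param network an `igraph` network.
#' @param path output file.
#' @export
write_interactions <- function(network, path) {
  el <- igraph::as_edgelist(network)
  readr::write_tsv(tibble(from = el[, 1], to = el[, 2]), path, col_names = FALSE)
  invisible(path)
}

#' Read named gene lists
#'
#' @param path file to read.
#' @param format `"lines"` (one symbol per line; the set is named after the
#'   file) or `"gmt"` (one set per line: name, description, symbols...).
#' @return a named list of character vectors. Symbols are trimmed,
#'   case-preserved and deduplicated; duplicates are logged.
#' @export
read_gene_list <- function(path, format = c("lines", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    oncotopo_abort(sprintf("cannot read gene list: '%s' does not exist", path), "io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    oncotopo_abort(sprintf("empty gene list: '%s'", path), "empty_geneset")
  }
  dedup <- function(symbols, name) {
    symbols <- stringr::str_trim(symbols)
    symbols <- symbols[nzchar(symbols)]
    n_dup <- sum(duplicated(symbols))
    if (n_dup > 0L) {
      rlang::inform(sprintf("read_gene_list: %d duplicate symbol(s) in set '%s'", n_dup, name))
    }
    unique(symbols)
  }
  if (format == "lines") {
    name <- tools::file_path_sans_ext(basename(path))
    out <- list(dedup(lines, name))
    names(out) <- name
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      oncotopo_abort(sprintf("malformed GMT row at line %d: need name, description, >=1 symbol", i), "parse")
    }
    dedup(f[3:length(f)], f[[1]])
  })
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (any(lengths(sets) == 0L)) {
    oncotopo_abort("empty gene set in GMT file", "empty_geneset")
  }
  sets
}

#' Write gene sets as a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], description[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' The 12 Pan-Cancer tumor-type labels
#'
#' @param merge_coadread merge colon and rectal adenocarcinoma into a single
#'   `"COAD/READ"` label, as the combined cohort is conventionally reported.
#' @return character vector of tumor-type labels.
#' @export
tumor_type_vocabulary <- function(merge_coadread = FALSE) {
  v <- c(
    "BLCA", "BRCA", "COAD", "READ", "GBM", "HNSC",
    "KIRC", "LAML", "LUAD", "LUSC", "OV", "UCEC"
  )
  if (merge_coadread) {
    v <- c("BLCA", "BRCA", "COAD/READ", "GBM", "HNSC", "KIRC", "LAML", "LUAD", "LUSC", "OV", "UCEC")
  }
  v
}

#' Column mapping for MAF-like mutation tables
#'
#' @param sample,gene,tumor_type,variant_class column names in the file.
#' @return a named list used by [read_mutation_table()].
#' @export
maf_dialect <- function(sample = "Tumor_Sample_Barcode",
                        gene = "Hugo_Symbol",
                        tumor_type = "tumor_type",
                        variant_class = "Variant_Classification") {
  list(sample = sample, gene = gene, tumor_type = tumor_type, variant_class = variant_class)
}

#' Construct a somatic-mutation incidence table
#'
#' Long-form records of (sample, gene, tumor type, variant class) plus the
#' sample manifest that carries denominators. Samples present in the manifest
#' but absent from the records are mutation-free samples that still count in
#' frequency denominators.
#'
#' @param records a data frame with columns `sample_id`, `gene`,
#'   `tumor_type`, `variant_class`.
#' @param samples optional manifest data frame with columns `sample_id`,
#'   `tumor_type`; defaults to the samples observed in `records`.
#' @param vocabulary allowed tumor-type labels; `NULL` disables the check.
#' @param strict error (rather than warn) on labels outside the vocabulary.
#' @return a `mutation_table` object.
#' @export
mutation_table <- function(records, samples = NULL,
                           vocabulary = tumor_type_vocabulary(),
                           strict = FALSE) {
  records <- as_tibble(records)
  need <- c("sample_id", "gene", "tumor_type", "variant_class")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    oncotopo_abort(sprintf("records lack column(s): %s", paste(missing_cols, collapse = ", ")), "schema")
  }
  records <- dplyr::mutate(records, dplyr::across(dplyr::all_of(need), as.character))
  if (is.null(samples)) {
    samples <- dplyr::distinct(records, .data$sample_id, .data$tumor_type)
  }
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "tumor_type") %in% names(samples))) {
    oncotopo_abort("sample manifest needs columns sample_id, tumor_type", "schema")
  }
  samples <- dplyr::distinct(
    dplyr::mutate(samples, dplyr::across(dplyr::everything(), as.character)),
    .data$sample_id, .data$tumor_type
  )
  orphan <- setdiff(records$sample_id, samples$sample_id)
  if (length(orphan) > 0L) {
    oncotopo_abort(sprintf(
      "%d sample(s) in records missing from the manifest (e.g. %s)",
      length(orphan), orphan[[1]]
    ), "schema")
  }
  if (!is.null(vocabulary)) {
    unknown <- setdiff(unique(c(records$tumor_type, samples$tumor_type)), vocabulary)
    if (length(unknown) > 0L) {
      msg <- sprintf(
        "tumor_type label(s) outside the declared vocabulary: %s",
        paste(unknown, collapse = ", ")
      )
      if (strict) oncotopo_abort(msg, "vocabulary") else rlang::warn(msg)
    }
  }
  structure(
    list(records = records, samples = samples, vocabulary = vocabulary),
    class = "mutation_table"
  )
}

#' @export
print.mutation_table <- function(x, ...) {
  cat(sprintf(
    "<mutation_table> %d records, %d samples, %d tumor types, %d genes\n",
    nrow(x$records), nrow(x$samples),
    dplyr::n_distinct(x$samples$tumor_type), dplyr::n_distinct(x$records$gene)
  ))
  invisible(x)
}

#' Read a MAF-like somatic mutation table
#'
#' @param path tab-separated file with one row per called variant.
#' @param dialect column mapping from [maf_dialect()].
#' @param manifest optional path to (or data frame of) a sample manifest with
#'   `sample_id` and `tumor_type` columns; lets mutation-free samples enter
#'   the denominators.
#' @param vocabulary,strict see [mutation_table()].
#' @param merge_coadread relabel COAD and READ records as `"COAD/READ"`.
#' @return a `mutation_table`.
#' @export
read_mutation_table <- function(path, dialect = maf_dialect(), manifest = NULL,
                                vocabulary = tumor_type_vocabulary(),
                                strict = FALSE, merge_coadread = FALSE) {
  if (!file.exists(path)) {
    oncotopo_abort(sprintf("cannot read mutation table: '%s' does not exist", path), "io")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(unlist(dialect), names(raw))
  if (length(missing_cols) > 0L) {
    oncotopo_abort(sprintf(
      "mutation table lacks mapped column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), "schema")
  }
  records <- tibble(
    sample_id = raw[[dialect$sample]],
    gene = stringr::str_trim(raw[[dialect$gene]]),
    tumor_type = raw[[dialect$tumor_type]],
    variant_class = raw[[dialect$variant_class]]
  )
  samples <- NULL
  if (!is.null(manifest)) {
    samples <- if (is.character(manifest)) {
      readr::read_tsv(manifest, col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE)
    } else {
      as_tibble(manifest)
    }
  }
  if (merge_coadread) {
    relabel <- function(x) ifelse(x %in% c("COAD", "READ"), "COAD/READ", x)
    records$tumor_type <- relabel(records$tumor_type)
    if (!is.null(samples)) samples$tumor_type <- relabel(samples$tumor_type)
    if (!is.null(vocabulary)) vocabulary <- tumor_type_vocabulary(merge_coadread = TRUE)
  }
  mutation_table(records, samples, vocabulary = vocabulary, strict = strict)
}

#' Write a mutation table (records + manifest) as MAF-like TSV
#'
#' @param table a `mutation_table`.
#' @param path output file for the variant records.
#' @param manifest_path optional output file for the sample manifest.
#' @param dialect column naming, see [maf_dialect()].
#' @export
write_mutation_table <- function(table, path, manifest_path = NULL, dialect = maf_dialect()) {
  stopifnot(inherits(table, "mutation_table"))
  out <- tibble(
    !!dialect$sample := table$records$sample_id,
    !!dialect$gene := table$records$gene,
    !!dialect$tumor_type := table$records$tumor_type,
    !!dialect$variant_class := table$records$variant_class
  )
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(manifest_path)) {
    readr::write_tsv(table$samples, manifest_path, progress = FALSE)
  }
  invisible(path)
}

#' Write a Steiner subnetwork to disk
#'
#' Formats: `"graphml"` (single file carrying node roles, mutation
#' frequencies, edge categories and tree membership), `"sif"` (one `pp`
#' relation per edge) and `"tsv"` (edge table with category columns). SIF and
#' TSV cannot hold node attributes, so both also write a `<path>.nodes.tsv`
#' sidecar; [read_subnetwork()] reads the pair back.
#'
#' @param subnet a `steiner_subnetwork` (see [induced_subnetwork()]).
#' @param path output file.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(subnet, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(subnet, "steiner_subnetwork"))
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) {
    oncotopo_abort(sprintf("cannot write subnetwork: directory '%s' does not exist", dirname(path)), "io")
  }
  nodes <- dplyr::arrange(subnet$nodes, .data$node)
  edges <- dplyr::arrange(subnet$edges, .data$from, .data$to)
  if (format == "graphml") {
    g <- subnetwork_graph(subnet)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  if (format == "sif") {
    con_lines <- sprintf("%s\tpp\t%s", edges$from, edges$to)
    isolated <- setdiff(nodes$node, unique(c(edges$from, edges$to)))
    writeLines(c(con_lines, isolated), path)
  } else {
    readr::write_tsv(edges, path, progress = FALSE)
  }
  readr::write_tsv(nodes, paste0(path, ".nodes.tsv"), progress = FALSE)
  invisible(path)
}

#' Read back a subnetwork written by [write_subnetwork()]
#'
#' @param path file written by [write_subnetwork()].
#' @param format the format it was written in.
#' @return a `steiner_subnetwork`.
#' @export
read_subnetwork <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    oncotopo_abort(sprintf("'%s' does not exist", path), "io")
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    mf <- igraph::V(g)$mutation_frequency
    mf[is.nan(mf)] <- NA_real_
    nodes <- tibble(
      node = igraph::V(g)$name,
      role = igraph::V(g)$role,
      mutation_frequency = mf
    )
    el <- igraph::as_edgelist(g)
    edges <- tibble(
      from = pmin(el[, 1], el[, 2]),
      to = pmax(el[, 1], el[, 2]),
      category = igraph::E(g)$category,
      in_tree = as.logical(igraph::E(g)$in_tree)
    )
    return(new_steiner_subnetwork(nodes, edges))
  }
  nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"),
    col_types = readr::cols(
      node = readr::col_character(),
      role = readr::col_character(),
      mutation_frequency = readr::col_double()
    ), progress = FALSE
  )
  if (format == "tsv") {
    edges <- readr::read_tsv(path,
      col_types = readr::cols(
        from = readr::col_character(),
        to = readr::col_character(),
        category = readr::col_character(),
        in_tree = readr::col_logical()
      ), progress = FALSE
    )
    return(new_steiner_subnetwork(nodes, edges))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  edge_rows <- fields[vapply(fields, length, 1L) >= 3L]
  from <- vapply(edge_rows, `[[`, "", 1L)
  to <- vapply(edge_rows, `[[`, "", 3L)
  edges <- tibble(from = pmin(from, to), to = pmax(from, to))
  # SIF carries no edge attributes: recover category from node roles, tree
  # membership is lost (recorded as NA).
  role_of <- setNames(nodes$role, nodes$node)
  edges$category <- edge_category(role_of[edges$from], role_of[edges$to])
  edges$in_tree <- NA
  new_steiner_subnetwork(nodes, edges)
}
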