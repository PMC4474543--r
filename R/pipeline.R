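pipeline_known_keys <- function() {
  c("seed", "outdir", "stages", "simulate", "inputs", "options", "steiner", "proximity")
}

pipeline_default_options <- function() {
  list(
    merge_coadread = FALSE,
    nonsilent_only = FALSE,
    normalized_betweenness = FALSE,
    strict_terminal_overlap = TRUE,
    max_distance = 8L
  )
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with keys
#' `seed`, `outdir`, `stages` (subset of `simulate`, `mutations`, `topology`,
#' `proximity`, `steiner`), `simulate` (a [synthetic_spec()] argument list),
#' `inputs` (paths: `network`, `gene_sets`, `mutations`, optional
#' `manifest`), `options` (flags: `merge_coadread`, `nonsilent_only`,
#' `normalized_betweenness`, `strict_terminal_overlap`, `max_distance`),
#' `steiner` (`terminal_a`, `terminal_b` set names) and `proximity`
#' (`source` set name). Unknown keys are rejected and referenced paths must
#' exist; validation happens before any computation.
#'
#' @param config named list or path to a YAML file.
#' @return the normalized config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      oncotopo_abort(sprintf("config file '%s' does not exist", config), "config")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), pipeline_known_keys())
  if (length(unknown) > 0L) {
    oncotopo_abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")), "config")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$outdir)) {
    oncotopo_abort("config needs an 'outdir'", "config")
  }
  all_stages <- c("simulate", "mutations", "topology", "proximity", "steiner")
  config$stages <- config$stages %||% all_stages
  bad <- setdiff(config$stages, all_stages)
  if (length(bad) > 0L) {
    oncotopo_abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")), "config")
  }
  opts <- pipeline_default_options()
  extra_opts <- setdiff(names(config$options %||% list()), names(opts))
  if (length(extra_opts) > 0L) {
    oncotopo_abort(sprintf("unknown option(s): %s", paste(extra_opts, collapse = ", ")), "config")
  }
  opts[names(config$options %||% list())] <- config$options
  config$options <- opts
  config$steiner <- config$steiner %||% list(terminal_a = "TSG", terminal_b = "OCG")
  config$proximity <- config$proximity %||% list(source = "Target")

  if (!"simulate" %in% config$stages) {
    need <- c("network", "gene_sets", "mutations")
    have <- names(config$inputs %||% list())
    missing_inputs <- setdiff(need, have)
    if ("mutations" %in% missing_inputs && !"mutations" %in% config$stages) {
      missing_inputs <- setdiff(missing_inputs, "mutations")
    }
    if (length(missing_inputs) > 0L) {
      oncotopo_abort(sprintf(
        "without a simulate stage, config$inputs must name: %s",
        paste(missing_inputs, collapse = ", ")
      ), "config")
    }
    for (nm in intersect(have, c("network", "gene_sets", "mutations", "manifest"))) {
      if (!file.exists(config$inputs[[nm]])) {
        oncotopo_abort(sprintf("input '%s' does not exist: %s", nm, config$inputs[[nm]]), "config")
      }
    }
  }
  config
}

pipeline_log <- function(level, stage, msg, ...) {
  rlang::inform(sprintf("[%s] %s: %s", level, stage, sprintf(msg, ...)))
}

#' Run the five-stage analysis pipeline
#'
#' Sequences input loading (or synthetic generation), catalog construction,
#' mutation-frequency profiling, topology profiling, target proximity and the
#' Klein-Ravi Steiner subnetwork, writing each stage's tables plus a
#' machine-readable `report.json` with md5 checksums of every output, the
#' seed, the package version and a hash of the configuration. Reruns with the
#' same config and seed are byte-identical. A stage failure aborts with the
#' stage name; outputs already written stay on disk next to an `INCOMPLETE`
#' marker.
#'
#' @param config see [pipeline_config()].
#' @param quiet suppress per-stage log lines.
#' @return the report, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(outdir, "INCOMPLETE")
  writeLines("pipeline running", marker)
  log <- if (quiet) function(...) invisible(NULL) else pipeline_log

  outputs <- character(0)
  report <- list(
    package = "oncotopo",
    version = as.character(utils::packageVersion("oncotopo")),
    seed = config$seed,
    stages = config$stages,
    config_hash = md5_of_object(config)
  )
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      oncotopo_abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), "stage")
    })
  }

  # --- inputs ---------------------------------------------------------------
  opts <- config$options
  if ("simulate" %in% config$stages) {
    run_stage("simulate", {
      spec_args <- config$simulate %||% list()
      spec_args$seed <- config$seed
      if (!is.null(spec_args$set_specs)) spec_args$set_specs <- dplyr::bind_rows(spec_args$set_specs)
      if (!is.null(spec_args$tumor_types)) spec_args$tumor_types <- dplyr::bind_rows(spec_args$tumor_types)
      spec <- do.call(synthetic_spec, spec_args)
      paths <- write_synthetic_study(spec, file.path(outdir, "inputs"))
      outputs <- c(outputs, paths)
      config$inputs <- list(
        network = paths[["network"]], gene_sets = paths[["sets"]],
        mutations = paths[["mutations"]], manifest = paths[["manifest"]]
      )
      log("INFO", "simulate", "wrote synthetic inputs (%d files)", length(paths))
    })
  }

  network <- run_stage("inputs", suppressMessages(
    read_interactions(config$inputs$network, format = "tsv", header = FALSE)
  ))
  sets <- run_stage("inputs", read_gene_list(config$inputs$gene_sets, format = "gmt"))
  sets <- sets[setdiff(names(sets), "Other")]
  log(
    "INFO", "inputs", "network: %d nodes, %d edges; %d gene sets",
    igraph::vcount(network), igraph::ecount(network), length(sets)
  )

  catalog <- run_stage("catalog", suppressMessages(build_catalog(network, sets)))
  run_stage("catalog", {
    write_catalog(catalog,
      gmt_path = file.path(outdir, "catalog.gmt"),
      json_path = file.path(outdir, "catalog.json")
    )
    outputs <- c(outputs, file.path(outdir, c("catalog.gmt", "catalog.json")))
    log("INFO", "catalog", "mapped sizes: %s",
        paste(sprintf("%s=%d", names(catalog$mapped), lengths(catalog$mapped)), collapse = ", "))
  })

  profile <- NULL
  if ("mutations" %in% config$stages) {
    profile <- run_stage("mutations", {
      if (is.null(config$inputs$mutations)) {
        oncotopo_abort("mutation stage enabled but no mutation table available", "config")
      }
      table <- read_mutation_table(config$inputs$mutations,
        manifest = config$inputs$manifest,
        merge_coadread = opts$merge_coadread
      )
      p <- set_frequency_profile(table, catalog, nonsilent_only = opts$nonsilent_only)
      readr::write_tsv(p$per_gene, file.path(outdir, "mutation_per_gene.tsv"), progress = FALSE)
      readr::write_tsv(p$per_set, file.path(outdir, "mutation_per_set.tsv"), progress = FALSE)
      ks_all <- lapply(setNames(nm = unique(p$per_gene$stratum)), function(s) {
        km <- compare_sets(p, stratum = s)
        lapply(split(km, seq_len(nrow(km))), as.list)
      })
      jsonlite::write_json(ks_all, file.path(outdir, "mutation_ks.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
      outputs <- c(outputs, file.path(outdir, c(
        "mutation_per_gene.tsv", "mutation_per_set.tsv", "mutation_ks.json"
      )))
      log("INFO", "mutations", "%d records over %d samples", nrow(table$records), nrow(table$samples))
      p
    })
  }

  topo <- NULL
  if ("topology" %in% config$stages) {
    topo <- run_stage("topology", {
      tp <- topology_profile(network, catalog,
        normalized_betweenness = opts$normalized_betweenness
      )
      readr::write_tsv(tp$per_node, file.path(outdir, "topology_per_node.tsv"), progress = FALSE)
      readr::write_tsv(tp$per_set, file.path(outdir, "topology_per_set.tsv"), progress = FALSE)
      readr::write_tsv(tp$ks, file.path(outdir, "topology_ks.tsv"), progress = FALSE)
      outputs <- c(outputs, file.path(outdir, c(
        "topology_per_node.tsv", "topology_per_set.tsv", "topology_ks.tsv"
      )))
      log("INFO", "topology", "profiled %d nodes", nrow(tp$per_node))
      tp
    })
  }

  if ("proximity" %in% config$stages) {
    run_stage("proximity", {
      src_name <- config$proximity$source
      if (!src_name %in% names(catalog$mapped)) {
        oncotopo_abort(sprintf("proximity source set '%s' not in catalog", src_name), "config")
      }
      src <- catalog$mapped[[src_name]]
      d <- min_distance_to_set(network, src)
      dp <- proximity_distribution(d, catalog, max_distance = opts$max_distance)
      readr::write_tsv(dp$per_set, file.path(outdir, "proximity_per_set.tsv"), progress = FALSE)
      dsum <- direct_interaction_summary(network, catalog, src)
      readr::write_tsv(dsum, file.path(outdir, "proximity_direct.tsv"), progress = FALSE)
      outputs <- c(outputs, file.path(outdir, c("proximity_per_set.tsv", "proximity_direct.tsv")))
      log("INFO", "proximity", "source '%s' (%d nodes)", src_name, length(src))
    })
  }

  if ("steiner" %in% config$stages) {
    run_stage("steiner", {
      a_name <- config$steiner$terminal_a
      b_name <- config$steiner$terminal_b
      term_a <- catalog$mapped[[a_name]]
      term_b <- catalog$mapped[[b_name]]
      if (is.null(term_a) || is.null(term_b)) {
        oncotopo_abort("steiner terminal set names not in catalog", "config")
      }
      inst <- steiner_instance(network, union(term_a, term_b), quiet = TRUE)
      nodes_kr <- klein_ravi(inst)
      subnet <- induced_subnetwork(network, nodes_kr, term_a, term_b,
        strict = opts$strict_terminal_overlap,
        terminal_set_names = c(a_name, b_name)
      )
      if (!is.null(profile)) {
        subnet <- attach_mutation_frequency(subnet, profile, quiet = TRUE)
        corr <- degree_frequency_correlation(subnet)
        jsonlite::write_json(
          list(r = corr$r, p_value = corr$p_value, n = corr$n),
          file.path(outdir, "steiner_correlation.json"),
          auto_unbox = TRUE, digits = NA
        )
        outputs <- c(outputs, file.path(outdir, "steiner_correlation.json"))
      }
      write_subnetwork(subnet, file.path(outdir, "steiner_subnetwork.tsv"), format = "tsv")
      comp <- edge_composition(subnet)
      jsonlite::write_json(
        list(
          counts = as.list(comp$counts),
          proportions = as.list(comp$proportions),
          total_edges = comp$total_edges,
          among_terminal_count = comp$among_terminal_count,
          among_terminal_percent = comp$among_terminal_percent
        ),
        file.path(outdir, "steiner_composition.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
      outputs <- c(outputs, file.path(outdir, c(
        "steiner_subnetwork.tsv", "steiner_subnetwork.tsv.nodes.tsv", "steiner_composition.json"
      )))
      log("INFO", "steiner", "%d nodes (%d linkers), %d edges",
          nrow(subnet$nodes), sum(subnet$nodes$role == "linker"), nrow(subnet$edges))
    })
  }

  outputs <- unname(outputs)
  report$outputs <- lapply(outputs, function(p) {
    list(path = sub(paste0("^", outdir, "/?"), "", p), md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(report, file.path(outdir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  unlink(marker)
  log("INFO", "report", "wrote %s", file.path(outdir, "report.json"))
  invisible(report)
}

md5_of_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(x), tmp)
  unname(tools::md5sum(tmp))
}
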