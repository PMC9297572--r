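## TSV writer with fixed formatting so pipeline outputs are byte-stable.
.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

## Schema of the pipeline YAML config: recognised top-level keys and the
## stages they drive. Unknown keys fail fast, naming the offender.
.PIPELINE_KEYS <- c("seed", "out", "sim", "stages", "window_size",
                    "profile_window_size", "profile_classes", "reference",
                    "top_k", "min_frac", "min_count", "max_gap")
.PIPELINE_STAGES <- c("simulate", "concordance", "profile", "overlap",
                      "phylostrata", "consensus", "synteny")

#' Validate a pipeline configuration
#'
#' @param config list as read from YAML.
#' @return The config with defaults filled in; errors name the offending key.
#' @export
validate_pipeline_config <- function(config) {
  bad <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop("config key 'seed' is required and must be numeric")
  if (is.null(config$stages)) config$stages <- .PIPELINE_STAGES
  bad_stage <- setdiff(config$stages, .PIPELINE_STAGES)
  if (length(bad_stage))
    stop("unknown stage(s) in config key 'stages': ",
         paste(bad_stage, collapse = ", "))
  config$window_size <- config$window_size %||% 1000
  config$profile_window_size <- config$profile_window_size %||% 5000
  config$profile_classes <- config$profile_classes %||% c("DNA", "LINE", "LTR")
  config$reference <- config$reference %||% "repeatmodeler2"
  config$top_k <- config$top_k %||% 20
  config$min_frac <- config$min_frac %||% 0.5
  config$min_count <- config$min_count %||% 20
  config$max_gap <- config$max_gap %||% 2
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the requested stages in dependency order -- simulate the fixture
#' suite, window concordance, density profiles, repeat-gene overlap,
#' phylostratigraphic contributions, classifier consensus, synteny screening
#' -- writing every result as TSV under `out_dir` together with a JSON run
#' manifest (seed, package version, stage list, output checksums) that makes
#' the run exactly reproducible.
#'
#' @param config path to a YAML configuration or an equivalent named list.
#'   Keys: `seed` (required); `stages` (subset of the stage names, default
#'   all); `sim` (overrides passed to [sim_config()]); `window_size`,
#'   `profile_window_size`, `profile_classes`, `reference`, `top_k`,
#'   `min_frac`, `min_count`, `max_gap`.
#' @param out_dir output directory (created if needed); `out` in the config
#'   is used when omitted.
#' @param quiet suppress stage progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  out_dir <- out_dir %||% config$out
  if (is.null(out_dir)) stop("config key 'out' (or out_dir) is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[teconcord] ", ...)
  stages <- config$stages
  cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))

  say("simulate")
  suite <- simulate_annotation_suite(cfg)
  gene_fix <- simulate_gene_fixture(cfg)
  hit_fix <- simulate_hit_table(cfg)
  lab_fix <- simulate_labels(cfg)
  ord_fix <- simulate_gene_orders(cfg)
  if ("simulate" %in% stages) {
    write_genome_index(suite$index, file.path(out_dir, "genome.tsv"))
    write_repeat_bed(suite$truth, file.path(out_dir, "truth.bed"))
    for (tn in names(suite$tools))
      write_repeat_bed(suite$tools[[tn]], file.path(out_dir, paste0(tn, ".bed")))
    write_gene_gff3(gene_fix$genes, file.path(out_dir, "genes.gff3"))
    write_repeat_bed(gene_fix$repeats, file.path(out_dir, "gene_repeats.bed"))
    .write_tsv(gene_fix$registry, file.path(out_dir, "gene_registry.tsv"))
    .write_tsv(hit_fix$hits, file.path(out_dir, "hit_table.tsv"))
    .write_tsv(hit_fix$overlaps, file.path(out_dir, "hit_overlaps.tsv"))
    .write_tsv(lab_fix$labels, file.path(out_dir, "labels.tsv"))
    for (sp in c("focal", "out1", "out2"))
      .write_tsv(ord_fix[[sp]], file.path(out_dir, paste0("order_", sp, ".tsv")))
  }

  if ("concordance" %in% stages) {
    say("concordance")
    grid <- make_windows(suite$index, config$window_size)
    pm <- binarize_windows(suite$tools, grid, suite$index)
    hc <- cluster_methods(pm)
    .write_tsv(data.frame(merge_a = hc$merge[, 1], merge_b = hc$merge[, 2],
                          height = hc$height),
               file.path(out_dir, "linkage.tsv"))
    .write_tsv(pattern_abundance(pm, config$top_k),
               file.path(out_dir, "patterns.tsv"))
    ref <- suite$tools[[config$reference]]
    agr <- vapply(setdiff(names(suite$tools), config$reference), function(tn)
      pairwise_agreement(suite$tools[[tn]], ref), numeric(1))
    .write_tsv(data.frame(method = names(agr), reference = config$reference,
                          agreement = unname(agr)),
               file.path(out_dir, "agreement.tsv"))
    .write_tsv(coverage_summary(suite$tools, suite$index),
               file.path(out_dir, "coverage.tsv"))
  }

  if ("profile" %in% stages) {
    say("profile")
    pgrid <- make_windows(suite$index, config$profile_window_size)
    .write_tsv(composition_summary(suite$truth),
               file.path(out_dir, "composition.tsv"))
    prof <- lapply(config$profile_classes, function(cl) {
      p <- density_profile(suite$truth, pgrid, cl, suite$index)
      p$te_class <- cl
      p
    })
    .write_tsv(do.call(rbind, prof), file.path(out_dir, "density.tsv"))
  }

  if ("overlap" %in% stages) {
    say("overlap")
    se <- gene_fix$genes[gene_fix$genes$transcript_id %in%
      names(which(table(gene_fix$genes$transcript_id) == 1)), ]
    se <- se[!se$gene_id %in%
      gene_fix$registry$gene_id[gene_fix$registry$kind == "multi"], ]
    contained <- fully_contained_overlaps(se, gene_fix$repeats)
    .write_tsv(contained, file.path(out_dir, "contained.tsv"))
    merged <- merge_isoforms(gene_fix$genes)
    cov <- exon_coverage_overlaps(merged, gene_fix$repeats,
                                  min_frac = config$min_frac)
    .write_tsv(cov, file.path(out_dir, "coverage_overlaps.tsv"))
    .write_tsv(superfamily_tally(contained, min_count = config$min_count),
               file.path(out_dir, "superfamily_tally.tsv"))
  }

  if ("phylostrata" %in% stages) {
    say("phylostrata")
    assign <- assign_age_classes(hit_fix$hits)
    .write_tsv(assign, file.path(out_dir, "age_classes.tsv"))
    .write_tsv(repeat_contribution_by_age(assign, hit_fix$overlaps),
               file.path(out_dir, "age_contributions.tsv"))
  }

  if ("consensus" %in% stages) {
    say("consensus")
    rep_cc <- consensus_report(lab_fix$labels, truth = lab_fix$truth)
    .write_tsv(data.frame(metric = c("unanimity_rate",
                                     paste0("error_", names(rep_cc$error_rates))),
                          value = c(rep_cc$unanimity_rate,
                                    unname(rep_cc$error_rates))),
               file.path(out_dir, "consensus.tsv"))
    mv <- majority_vote(lab_fix$labels)
    .write_tsv(mv, file.path(out_dir, "majority_vote.tsv"))
  }

  if ("synteny" %in% stages) {
    say("synteny")
    calls <- detect_lineage_specific_insertions(
      ord_fix$focal, ord_fix$out1, ord_fix$out2,
      target_families = cfg$insertion_family, max_gap = config$max_gap)
    .write_tsv(calls, file.path(out_dir, "insertions.tsv"))
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "teconcord",
    version = as.character(utils::packageVersion("teconcord")),
    seed = config$seed,
    stages = stages,
    checksums = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
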