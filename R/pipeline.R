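#' Assemble a pipeline configuration
#'
#' A pipeline run is driven by a single configuration: input paths (or a
#' simulator scenario), the sample map, filter settings, class preset,
#' specificity window and seed. Configurations can be given as an R list or a
#' YAML file with the same fields.
#'
#' @param substrate_fasta Path to the substrate FASTA (single record);
#'   ignored when `simulate` is given.
#' @param peptide_table Path to the peptide TSV; ignored when `simulate` is
#'   given.
#' @param sample_map Data frame (or TSV path) mapping intensity columns to
#'   condition/replicate/time.
#' @param pdb,chain Optional structure coordinate file and chain id.
#' @param msa Optional multiple sequence alignment (FASTA/Clustal), reference
#'   row first.
#' @param filter A [filter_config()] (or list of its arguments).
#' @param class_preset `"anxa1"` or `"mdh"` class edges.
#' @param window Specificity window half-width.
#' @param numbering_offset Recombinant-to-native numbering offset.
#' @param simulate Optional simulator block: a list with (all optional)
#'   `n_molecules`, `time_points`, `replicates`, `sigma_lognormal`,
#'   `dropout_probability`, `protease_multiplier`; when present the default
#'   scenario is simulated instead of reading input files.
#' @param seed Integer seed recorded in all outputs and driving any
#'   simulation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(substrate_fasta = NULL, peptide_table = NULL,
                            sample_map = NULL, pdb = NULL, chain = "A",
                            msa = NULL, filter = filter_config(),
                            class_preset = "anxa1", window = 5L,
                            numbering_offset = 0L, simulate = NULL,
                            seed = 1L) {
  if (!inherits(filter, "filter_config")) filter <- do.call(filter_config, filter)
  structure(
    list(
      substrate_fasta = substrate_fasta, peptide_table = peptide_table,
      sample_map = sample_map, pdb = pdb, chain = chain, msa = msa,
      filter = filter, class_preset = class_preset, window = as.integer(window),
      numbering_offset = as.integer(numbering_offset),
      simulate = simulate, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full targeted-proteolysis pipeline
#'
#' Executes, in order: input loading (or simulation), replicate QC, score and
#' slope-homogeneity filtering, peptide mapping, fragment grouping, relative
#' cut frequencies, site classification, specificity profiling, optional
#' structure/conservation annotation and cleavage-event ordering; writes every
#' result as TSV/JSON into `output_dir` together with a run manifest carrying
#' the configuration hash and seed. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()], a list of its arguments, or a YAML
#'   path.
#' @param output_dir Directory for outputs (created if needed); `NULL` skips
#'   writing.
#' @return A list (invisibly if writing) with `substrate`, `peptides`, `qc`,
#'   `relevance`, `fragments`, `profiles`, `classes`, `specificity`,
#'   `consensus`, `order`, `timeline`, `annotation`, `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  cfg_hash <- digest::digest(unclass(config))
  inform(paste0("pipeline: config hash ", substr(cfg_hash, 1, 12), ", seed ", config$seed))

  sim <- NULL
  if (!is.null(config$simulate)) {
    tab <- pipeline_stage("simulate", {
      s <- config$simulate
      gt <- scenario_pseudo_anxa1(n_molecules = s$n_molecules %||% 2000)
      simulate_peptide_table(
        gt,
        time_points = s$time_points %||% c(0, 15, 30, 60, 120, 180, 300, 600, 1200, 1800, 3600),
        replicates = s$replicates %||% 4,
        sigma_lognormal = s$sigma_lognormal %||% 0.5,
        dropout_probability = s$dropout_probability %||% 0.2,
        protease_multiplier = s$protease_multiplier %||% 1,
        seed = config$seed
      )
    })
    substrate <- tab$ground_truth$substrate
    peptides <- tab$peptides
    sim <- tab$simulation
  } else {
    substrate <- pipeline_stage(
      "read_substrate",
      read_substrate_fasta(config$substrate_fasta, config$numbering_offset)
    )
    sample_map <- pipeline_stage("sample_map", {
      if (is.character(config$sample_map)) {
        readr::read_tsv(config$sample_map, show_col_types = FALSE, progress = FALSE)
      } else {
        as_tibble(config$sample_map)
      }
    })
    peptides <- pipeline_stage(
      "read_peptides",
      read_peptide_table(config$peptide_table, sample_map)
    )
  }
  fc <- config$filter

  qc <- pipeline_stage("replicate_qc", {
    replicate_qc(peptides, pearson_cutoff = fc$pearson_cutoff, transform = fc$transform)
  })
  peptides_qc <- apply_qc(peptides, qc)

  peptides_scored <- pipeline_stage(
    "score_filter", score_filter(peptides_qc, fc$min_score)
  )
  has_controls <- any(peptides_scored$is_control)
  if (!has_controls) {
    warn("no control samples in configuration; relevance and significance gates disabled")
  }
  relevance <- if (has_controls) {
    pipeline_stage("slope_homogeneity", {
      peptide_relevance(peptides_scored,
        alpha = fc$alpha, transform = fc$transform, adjust = fc$adjust
      )
    })
  } else {
    tibble(
      sequence = unique(peptides_scored$sequence),
      f_statistic = NA_real_, p_value = NA_real_, testable = FALSE,
      p_adjusted = NA_real_, relevant = TRUE
    )
  }
  relevant <- filter(relevance, .data$relevant)$sequence
  peptides_rel <- filter(peptides_scored, .data$sequence %in% relevant)

  peptides_mapped <- pipeline_stage(
    "map_peptides", map_peptides(peptides_rel, substrate)
  )
  fragments <- pipeline_stage("fragments", fragment_maps(peptides_mapped, substrate))
  profiles <- pipeline_stage("cut_frequency", {
    relative_cut_frequency(peptides_mapped, substrate,
      alpha = fc$alpha, both_bonds = fc$both_bonds
    )
  })
  classes <- pipeline_stage(
    "classes", classify_sites(profiles, class_edges(config$class_preset))
  )
  times <- attr(profiles, "time_points")
  specificity <- pipeline_stage("specificity", {
    bind_rows(map(times[times > 0], function(tp) {
      m <- aa_distribution(profiles, substrate, tp, width = config$window)
      mutate(as_tibble(m), time_s = tp)
    }))
  })
  consensus_tbl <- pipeline_stage("consensus", {
    last <- max(times)
    m <- aa_distribution(profiles, substrate, last, width = config$window)
    mutate(consensus(m), time_s = last)
  })
  order <- pipeline_stage("order_events", order_events(profiles))
  timeline <- pipeline_stage("timeline", fragment_timeline(order, substrate))

  annotation <- pipeline_stage("annotation", {
    str <- if (!is.null(config$pdb)) read_structure(config$pdb, config$chain) else NULL
    annotate_profiles(profiles, substrate, structure = str, msa = config$msa)
  })

  result <- list(
    substrate = substrate, peptides = peptides, qc = qc, relevance = relevance,
    fragments = fragments, profiles = profiles, classes = classes,
    specificity = specificity, consensus = consensus_tbl, order = order,
    timeline = timeline, annotation = annotation, simulation = sim
  )
  manifest <- list(
    package = "proteocut",
    version = as.character(utils::packageVersion("proteocut")),
    config_hash = cfg_hash,
    seed = config$seed
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_tsv(as_tibble(x), file.path(output_dir, f), progress = FALSE)
    w(qc, "qc_report.tsv")
    w(relevance, "filter_report.tsv")
    w(fragments, "fragments.tsv")
    w(as_tibble(profiles), "site_profiles.tsv")
    w(classes, "site_classes.tsv")
    w(specificity, "specificity.tsv")
    w(consensus_tbl, "consensus.tsv")
    w(as_tibble(order), "event_order.tsv")
    w(annotation, "annotation.tsv")
    jsonlite::write_json(
      list(manifest = manifest, timeline = as_tibble(timeline)),
      file.path(output_dir, "timeline.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    manifest$outputs <- sort(list.files(output_dir))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  result$manifest <- manifest
  invisible(result)
}
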