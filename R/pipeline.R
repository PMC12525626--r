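#' Read a pipeline run configuration
#'
#' A flat YAML file with input paths (`fasta`, `phospho`,
#' `annotations`, optional `pssm` and `disorder`) and parameters
#' (`tts_threshold`, `min_disorder`, `min_neglog10_p`, `min_fold`,
#' `min_term_size`, `output_dir`). Missing parameters take the default
#' analysis profile: TTS threshold 0.385, reporting filters
#' -log10 p > 4 and fold >= 4.
#'
#' @param path YAML file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("fasta", "phospho", "annotations", "pssm", "disorder")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      candidate <- file.path(base, cfg[[key]])
      if (file.exists(candidate)) cfg[[key]] <- candidate
    }
  }
  cfg
}

default_config <- function(cfg) {
  defaults <- list(tts_threshold = 0.385, min_neglog10_p = 4,
                   min_fold = 4, min_term_size = 1L,
                   min_disorder = NULL, pssm = NULL, disorder = NULL)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[k] <- defaults[k]
  }
  cfg
}

#' Run the motif-to-enrichment pipeline
#'
#' Executes scan -> phospho cross-reference -> arm census ->
#' over-representation -> display filter from one configuration,
#' writing per-stage TSVs, a log and a JSON manifest (parameters, input
#' checksums, row counts). Identical configuration and inputs produce
#' byte-identical outputs. When the phosphosite table yields no
#' position-8 serine/threonine hosts, or no annotation table is
#' configured, the enrichment stage is skipped with a notice.
#'
#' @param config A configuration list (see [read_run_config()]) or a
#'   path to a YAML configuration file.
#' @param out_dir Output directory; defaults to `config$output_dir`.
#' @return Invisibly, a list with the stage results (`matches`,
#'   `xrefs`, `census`, `enrichment`, `enrichment_filtered`) and the
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- default_config(config)
  out_dir <- out_dir %||% config$output_dir
  if (is.null(out_dir)) stop_input("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  inputs <- Filter(Negate(is.null),
                   config[c("fasta", "phospho", "annotations",
                            "pssm", "disorder")])
  missing <- unlist(inputs)[!file.exists(unlist(inputs))]
  if (length(missing) > 0) {
    stop_input("[config] input path(s) not found: ",
               paste(missing, collapse = ", "))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note("ERROR [", name, "] ", conditionMessage(e))
      writeLines(log_lines, file.path(out_dir, "pipeline.log"))
      stop_input("[", name, "] ", conditionMessage(e))
    })
  }

  pssm <- stage("pssm", {
    if (is.null(config$pssm)) build_default_pssm()
    else read_tbm_pssm(config$pssm)
  })
  records <- stage("scan", read_fasta(config$fasta))
  matches <- stage("scan",
                   scan_proteome(records, pssm, config$tts_threshold))
  note("scan: ", nrow(records), " proteins, ", nrow(matches),
       " matches at TTS >= ", config$tts_threshold)
  if (!is.null(config$disorder)) {
    matches <- stage("disorder", {
      d <- read_tsv(config$disorder)
      dis <- lapply(split(d, d$protein_id), function(g)
        g$score[order(g$position)])
      filter_by_disorder(matches, dis,
                         config$min_disorder %||% 0.5)
    })
    note("disorder filter: ", nrow(matches), " matches kept")
  }
  write_tsv(matches, file.path(out_dir, "matches.tsv"))

  events <- stage("xref", read_phospho_table(config$phospho))
  xrefs <- stage("xref", map_events_to_motifs(matches, events))
  census <- census_by_arm(xrefs)
  note("xref: ", nrow(events), " events; census motifs ",
       paste(names(census$motif_counts), census$motif_counts,
             sep = "=", collapse = " "))
  write_tsv(xrefs, file.path(out_dir, "xref.tsv"))
  write_tsv(data.frame(arm = names(census$motif_counts),
                       motif_count = as.integer(census$motif_counts),
                       protein_count =
                         as.integer(census$protein_counts)),
            file.path(out_dir, "census.tsv"))

  enr <- NULL
  enr_filtered <- NULL
  study <- census$proteins_pS8_pT8
  if (is.null(config$annotations)) {
    note("enrich: skipped (no annotation table configured)")
  } else if (length(study) == 0) {
    note("enrich: skipped (no pS8/pT8 host proteins)")
  } else {
    enr <- stage("enrich", {
      ann <- read_annotations(config$annotations)
      population <- unique(c(ann$protein_id, study))
      enrich(study, ann, population = population,
             min_term_size = config$min_term_size)
    })
    enr_filtered <- display_filter(enr, config$min_neglog10_p,
                                   config$min_fold)
    note("enrich: ", nrow(enr), " terms tested, ",
         nrow(enr_filtered), " pass the display filter")
    write_enrichment(enr, file.path(out_dir, "enrichment.tsv"))
    write_enrichment(enr_filtered,
                     file.path(out_dir, "enrichment_filtered.tsv"))
  }

  manifest <- list(
    package = "phosphoTBM",
    version = as.character(utils::packageVersion("phosphoTBM")),
    parameters = config[c("tts_threshold", "min_disorder",
                          "min_neglog10_p", "min_fold",
                          "min_term_size")],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    row_counts = list(
      proteins = nrow(records),
      matches = nrow(matches),
      phospho_events = nrow(events),
      arm_motifs = as.list(census$motif_counts),
      arm_proteins = as.list(census$protein_counts),
      study_proteins = length(study),
      terms_tested = if (is.null(enr)) 0L else nrow(enr),
      terms_displayed = if (is.null(enr_filtered)) 0L
                        else nrow(enr_filtered)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(matches = matches, xrefs = xrefs, census = census,
                 enrichment = enr, enrichment_filtered = enr_filtered,
                 manifest = manifest))
}
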