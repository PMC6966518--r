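#' Assemble a pipeline configuration
#'
#' Reads a YAML file (or takes a list) and merges it over the pipeline
#' defaults, which mirror the analysis constants: score threshold 0.65,
#' conservation tiers 100/99/97\%, H/L ratio threshold 3, alpha 0.05,
#' curation window 15 columns, exact residue matching, seed 1. Input and
#' output paths live under \code{input} and \code{out_dir}.
#'
#' @param config Path to a YAML file, a list, or \code{NULL} for defaults.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config = NULL) {
  if (inherits(config, "pipeline_config")) return(config)
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    if (!file.exists(config)) {
      gm_stop(sprintf("config file not found: %s", config), "io")
    }
    y <- yaml::read_yaml(config)
    if (is.null(y)) list() else y
  } else if (is.list(config)) {
    config
  } else {
    gm_stop("config must be a YAML path or a list", "config")
  }
  defaults <- list(
    out_dir = ".",
    seed = 1L,
    score_threshold = 0.65,
    tier_fractions = c("100%" = 1.00, "99%" = 0.99, "97%" = 0.97),
    residue_match = "exact",
    ratio_threshold = 3,
    alpha = 0.05,
    window = 15L,
    start_tol = 0L,
    reference_family = NULL,
    category_rules = c(myosin = "myosin"),
    normalization = "none",
    input = list(),
    simulate = list()
  )
  cfg <- utils::modifyList(defaults, user)
  if (!is.null(cfg$tier_fractions)) {
    cfg$tier_fractions <- unlist(cfg$tier_fractions)
  }
  cfg$category_rules <- unlist(cfg$category_rules)
  # range checks on the documented thresholds
  if (cfg$score_threshold <= 0 || cfg$score_threshold >= 1) {
    gm_stop("score_threshold must lie in (0, 1)", "config")
  }
  if (cfg$ratio_threshold <= 0) gm_stop("ratio_threshold must be > 0", "config")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) gm_stop("alpha must lie in (0, 1)", "config")
  structure(cfg, class = "pipeline_config")
}

# provenance line written at the top of every tabular output
gm_provenance <- function(cfg, stage) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  yaml::write_yaml(unclass(cfg), tf)
  hash <- unname(md5sum(tf))
  list(version = as.character(packageVersion("gelmap")),
       stage = stage, config_md5 = hash, seed = cfg$seed,
       header = sprintf("# gelmap %s %s config_md5=%s seed=%s",
                        as.character(packageVersion("gelmap")), stage,
                        hash, cfg$seed))
}

gm_require_inputs <- function(cfg, keys) {
  for (key in keys) {
    p <- cfg$input[[key]]
    if (is.null(p)) {
      gm_stop(sprintf("config is missing input path '%s'", key), "config")
    }
    if (!file.exists(p)) {
      gm_stop(sprintf("input file not found: %s", p), "io")
    }
  }
  invisible(TRUE)
}

gm_out <- function(cfg, name) file.path(cfg$out_dir, name)

#' Run one pipeline stage
#'
#' Orchestrates the analyses as named stages over file inputs and outputs:
#' \describe{
#'   \item{simulate}{emit synthetic alignment, site predictions, signal
#'     score summary, peptide table, profile pair and the ground truth}
#'   \item{curate}{alignment-membership filtering of an aligned FASTA}
#'   \item{liftover}{site positions -> alignment columns -> reference
#'     coordinates, as a table}
#'   \item{conserve}{conservation tally and tiering on the reference}
#'   \item{sigcompare}{family comparison of S-mean scores with letters}
#'   \item{degradome}{H/L filtering, P1' classification and summary}
#'   \item{coloc}{correlation of a two-channel intensity profile table}
#' }
#' Outputs are deterministic for a fixed config (all randomness flows from
#' \code{config$seed}) and every output starts with a provenance header
#' (package version, config hash, seed). Inputs are never modified. On any
#' validation failure a classed \code{gelmap_*_error} condition is raised
#' before outputs are written.
#'
#' @param stage One of \code{"simulate"}, \code{"curate"},
#'   \code{"liftover"}, \code{"conserve"}, \code{"sigcompare"},
#'   \code{"degradome"}, \code{"coloc"}.
#' @param config A \code{\link{pipeline_config}}, YAML path or list. Stage
#'   inputs are looked up in \code{config$input} (keys \code{alignment},
#'   \code{sites}, \code{signal_summary}, \code{peptides},
#'   \code{profiles}, \code{reference_id}).
#' @return Invisibly a named character vector of output paths.
#' @export
run_stage <- function(stage = c("simulate", "curate", "liftover", "conserve",
                                "sigcompare", "degradome", "coloc"),
                      config = NULL) {
  stage <- match.arg(stage)
  cfg <- pipeline_config(config)
  prov <- gm_provenance(cfg, stage)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(
    stage,
    simulate = stage_simulate(cfg, prov),
    curate = stage_curate(cfg, prov),
    liftover = stage_liftover(cfg, prov),
    conserve = stage_conserve(cfg, prov),
    sigcompare = stage_sigcompare(cfg, prov),
    degradome = stage_degradome(cfg, prov),
    coloc = stage_coloc(cfg, prov))
  invisible(out)
}

with_provenance <- function(text, prov) paste0(prov$header, "\n", text)

write_json_result <- function(obj, prov, path) {
  obj <- c(list(provenance = prov[c("version", "stage", "config_md5", "seed")]),
           obj)
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                           digits = NA, na = "null")), path)
  path
}

stage_simulate <- function(cfg, prov) {
  sim <- cfg$simulate
  fp_args <- sim$family
  if (!is.null(fp_args$planted_sites)) {
    fp_args$planted_sites <- as.data.frame(fp_args$planted_sites)
  }
  fp <- do.call(family_sim_params,
                c(fp_args, if (is.null(fp_args$seed)) list(seed = cfg$seed)))
  fam <- simulate_orthologue_family(fp)

  fam_specs <- if (!is.null(sim$signal_families)) {
    as.data.frame(sim$signal_families)
  } else {
    data.frame(family = c("MMP2", "MMP9", "Vtn"),
               n = c(60L, 60L, 60L),
               mean = c(0.795, 0.93, 0.95),
               spread = c(0.06, 0.03, 0.02))
  }
  sig <- simulate_signal_scores(fam_specs, seed = cfg$seed)

  dp_args <- sim$degradome
  dp <- do.call(degradome_sim_params,
                c(dp_args, if (is.null(dp_args$seed)) list(seed = cfg$seed)))
  deg <- simulate_degradome(dp)

  pr_args <- sim$profiles
  if (is.null(pr_args)) pr_args <- list(period = 20, phase = 0.5, noise_sd = 0.2)
  if (is.null(pr_args$seed)) pr_args$seed <- cfg$seed
  prof <- do.call(simulate_profiles, pr_args)

  paths <- c(alignment = gm_out(cfg, "alignment.fasta"),
             sites = gm_out(cfg, "site_predictions.tsv"),
             signal_summary = gm_out(cfg, "signal_scores.txt"),
             peptides = gm_out(cfg, "peptides.tsv"),
             profiles = gm_out(cfg, "profiles.tsv"),
             truth = gm_out(cfg, "truth.json"))
  writeLines(fam$fasta, paths[["alignment"]], sep = "")
  writeLines(with_provenance(write_site_predictions(fam$calls), prov),
             paths[["sites"]], sep = "")
  writeLines(with_provenance(write_signalp_summary(sig), prov),
             paths[["signal_summary"]], sep = "")
  writeLines(with_provenance(write_peptide_table(deg$records), prov),
             paths[["peptides"]], sep = "")
  prof_lines <- c("channel_a\tchannel_b",
                  sprintf("%s\t%s",
                          format(prof$channel_a, digits = 8, trim = TRUE),
                          format(prof$channel_b, digits = 8, trim = TRUE)))
  writeLines(with_provenance(paste0(paste(prof_lines, collapse = "\n"), "\n"),
                             prov), paths[["profiles"]], sep = "")
  write_json_result(list(
    reference_id = fam$reference_id,
    site_presence_fraction = as.list(fam$truth$presence_fraction),
    degradome_myosin_count = sum(deg$truth$is_myosin)), prov,
    paths[["truth"]])
  paths
}

stage_curate <- function(cfg, prov) {
  gm_require_inputs(cfg, "alignment")
  recs <- read_fasta(cfg$input$alignment)
  crep <- filter_alignment_members(recs, window = cfg$window,
                                   start_tol = cfg$start_tol)
  paths <- c(report = gm_out(cfg, "curation_report.tsv"),
             retained = gm_out(cfg, "curated.fasta"))
  writeLines(with_provenance(write_curation_report(crep), prov),
             paths[["report"]], sep = "")
  writeLines(write_fasta(crep$records), paths[["retained"]], sep = "")
  paths
}

gapmaps_from_fasta <- function(path) {
  recs <- read_fasta(path)
  maps <- lapply(seq_len(nrow(recs)), function(i) {
    build_gapmap(recs$sequence[i], id = recs$id[i])
  })
  names(maps) <- recs$id
  list(records = recs, maps = maps)
}

stage_liftover <- function(cfg, prov) {
  gm_require_inputs(cfg, c("alignment", "sites"))
  gf <- gapmaps_from_fasta(cfg$input$alignment)
  ref <- cfg$input$reference_id
  if (is.null(ref)) ref <- gf$records$id[1L]
  calls <- load_site_predictions(cfg$input$sites,
                                 setNames(gf$records$sequence, gf$records$id))
  path <- c(liftover = gm_out(cfg, "liftover.tsv"))
  tab <- liftover_table(calls, gf$maps, ref)
  lines <- c("id\tposition\tcolumn\tref_pos",
             sprintf("%s\t%d\t%d\t%s", tab$id, tab$position, tab$column,
                     ifelse(is.na(tab$ref_pos), "NA", tab$ref_pos)))
  writeLines(with_provenance(paste0(paste(lines, collapse = "\n"), "\n"), prov),
             path[["liftover"]], sep = "")
  path
}

stage_conserve <- function(cfg, prov) {
  gm_require_inputs(cfg, c("alignment", "sites"))
  gf <- gapmaps_from_fasta(cfg$input$alignment)
  ref <- cfg$input$reference_id
  if (is.null(ref)) ref <- gf$records$id[1L]
  calls <- load_site_predictions(cfg$input$sites,
                                 setNames(gf$records$sequence, gf$records$id))
  params <- conservation_params(score_threshold = cfg$score_threshold,
                                tier_fractions = cfg$tier_fractions,
                                residue_match = cfg$residue_match)
  sites <- conservation_tally(calls, gf$maps, ref, params)
  tiers <- attr(sites, "tiers")
  paths <- c(sites = gm_out(cfg, "conserved_sites.tsv"),
             summary = gm_out(cfg, "conservation.json"))
  writeLines(with_provenance(write_conserved_sites(sites), prov),
             paths[["sites"]], sep = "")
  write_json_result(list(
    n_orthologues = attr(sites, "n_orthologues"),
    n_sites = nrow(sites),
    min_counts = as.list(tiers$min_counts),
    cumulative = as.list(tiers$cumulative),
    bands = as.list(tiers$bands)), prov, paths[["summary"]])
  paths
}

stage_sigcompare <- function(cfg, prov) {
  gm_require_inputs(cfg, "signal_summary")
  recs <- parse_signalp_summary(cfg$input$signal_summary)
  cmp <- family_comparison(recs, alpha = cfg$alpha,
                           reference_family = cfg$reference_family)
  paths <- c(summary = gm_out(cfg, "signal_comparison.tsv"),
             json = gm_out(cfg, "signal_comparison.json"))
  txt <- write_family_comparison(cmp)
  writeLines(with_provenance(txt$tsv, prov), paths[["summary"]], sep = "")
  write_json_result(list(alpha = cmp$alpha, summary = cmp$summary,
                         p_adj = cmp$p_adj), prov, paths[["json"]])
  paths
}

stage_degradome <- function(cfg, prov) {
  gm_require_inputs(cfg, "peptides")
  recs <- parse_peptide_table(cfg$input$peptides)
  params <- degradome_params(ratio_threshold = cfg$ratio_threshold,
                             category_rules = cfg$category_rules,
                             normalization = cfg$normalization)
  summ <- summarize_degradome(recs, params)
  paths <- c(summary = gm_out(cfg, "degradome.json"),
             passing = gm_out(cfg, "degradome_passing.tsv"))
  txt <- write_degradome_summary(summ)
  writeLines(txt$json, paths[["summary"]])
  writeLines(with_provenance(txt$tsv, prov), paths[["passing"]], sep = "")
  paths
}

stage_coloc <- function(cfg, prov) {
  gm_require_inputs(cfg, "profiles")
  prof <- read_profiles(cfg$input$profiles)
  r <- pearson_r(prof$channel_a, prof$channel_b)
  path <- c(coloc = gm_out(cfg, "coloc.json"))
  write_json_result(list(r = r, n = nrow(prof), method = "pearson"),
                    prov, path[["coloc"]])
  path
}
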