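#' End-to-end monoclonal sequencing-error audit
#'
#' Runs the full monoclonal workflow: simulate reads under the trifurcated
#' 27-reaction study design (or load a FASTQ), extract and validate CDR3s,
#' profile errors across phred cutoffs, build the position-by-substitution
#' matrix with lane CV and per-cell ANOVA, test error complementation,
#' screen direction skew, and cull single-mismatch sequences across a
#' cutoff grid. All randomness flows from one root seed.
#'
#' @param template a `template_spec` (the monoclonal truth).
#' @param model an `error_model`; lane multipliers from the study design are
#'   applied unless the model already carries some.
#' @param n_reads_per_reaction reads per sequencing reaction (27 reactions).
#' @param q_cutoffs phred cutoffs for profiling.
#' @param cull_cutoffs relative-frequency cutoffs for monoclonal culling.
#' @param seed root seed.
#' @param out_dir optional directory; when given, TSV/JSON reports and a
#'   manifest are written there.
#' @return list with elements `sim`, `extraction`, `profile`, `sub_matrix`,
#'   `rates_by_sample`, `lane_cv`, `lane_anova`, `per_nt_rates`,
#'   `complementation`, `direction_skew`, `culling` (one `cull_report` per
#'   cutoff), and `manifest`.
#' @export
run_monoclonal_audit <- function(template,
                                 model = error_model(),
                                 n_reads_per_reaction = 500L,
                                 q_cutoffs = c(0, 10, 20, 30),
                                 cull_cutoffs = c(0, 0.001, 0.01, 0.1, 1),
                                 seed = 1L,
                                 out_dir = NULL) {
  stopifnot(inherits(template, "template_spec"))
  preset <- preset_study_design(n_reads_per_reaction)
  if (is.null(model$lane_multipliers))
    model$lane_multipliers <- preset$lane_multipliers
  sim <- simulate_reads(template, model, design = preset$design, seed = seed)
  ex <- extract_cdr3(sim$reads, template_flanks(template))
  prof <- profile_errors(ex$records, template$cdr3, q_cutoffs = q_cutoffs)
  smat <- substitution_matrix(ex$records, template$cdr3,
                              by = c("lane", "orientation"))
  by_sample <- substitution_matrix(ex$records, template$cdr3,
                                   by = c("lane", "sample_path"))
  cvs <- lane_cv(by_sample)
  aov <- lane_anova(by_sample)
  rates <- per_nt_substitution_rates(smat)
  spec0 <- prof$spectrum[prof$spectrum$q_cutoff == min(q_cutoffs), ]
  n_total0 <- prof$summary$total[which.min(prof$summary$q_cutoff)]
  comp <- if (nrow(spec0) && n_total0 > 0) {
    sp <- rbind(data.frame(m = 0L,
                           count = n_total0 - sum(spec0$count)),
                data.frame(m = spec0$m, count = spec0$count))
    complementation_test(sp, n = nchar(template$cdr3))
  } else NULL
  tab <- build_clone_table(ex$records)
  skew <- if (nrow(tab) > 1L) direction_skew_screen(tab) else NULL
  culls <- lapply(cull_cutoffs, function(ct)
    cull_monoclonal(tab, template$cdr3, ct))
  names(culls) <- as.character(cull_cutoffs)
  manifest <- list(
    mode = "monoclonal_audit", seed = seed, template = template$name,
    n_reads = nrow(sim$reads), n_accepted = nrow(ex$records),
    n_rejected = nrow(ex$rejects), q_cutoffs = q_cutoffs,
    cull_cutoffs = cull_cutoffs, n_reactions = nrow(preset$design))
  out <- list(sim = sim, extraction = ex, profile = prof, sub_matrix = smat,
              rates_by_sample = by_sample, lane_cv = cvs, lane_anova = aov,
              per_nt_rates = rates, complementation = comp,
              direction_skew = skew, culling = culls, manifest = manifest)
  if (!is.null(out_dir)) .write_bundle(out, out_dir)
  out
}

#' End-to-end polyclonal filtering analysis
#'
#' Simulates a polyclonal repertoire (power-law clone abundances over
#' `n_clones` templates), extracts CDR3s, builds clonotype tables at the
#' requested phred cutoffs, tallies lower-frequency single-mismatch
#' sequences around the top index clonotypes across a cutoff grid, and
#' reports richness (unique clonotypes, ACE) before and after filtering.
#'
#' @param n_clones number of simulated clonotypes.
#' @param model an `error_model`.
#' @param n_reads total reads.
#' @param q_cutoffs phred cutoffs for the paired tables (default `c(0, 30)`).
#' @param cutoffs relative-frequency cutoffs for the neighbor tallies.
#' @param top_k number of index clonotypes (default 20).
#' @param rare_cutoff ACE rare/abundant boundary (default 10).
#' @param seed root seed.
#' @param out_dir optional report directory.
#' @return list with `sim`, `extraction`, `tables` (one `clone_table` per
#'   cutoff), `culling` (per cutoff), `richness`, `manifest`.
#' @export
run_polyclonal_filter <- function(n_clones = 200L,
                                  model = error_model(),
                                  n_reads = 20000L,
                                  q_cutoffs = c(0, 30),
                                  cutoffs = seq(0.001, 0.01, by = 0.001),
                                  top_k = 20L,
                                  rare_cutoff = 10L,
                                  seed = 1L,
                                  out_dir = NULL) {
  set.seed(as.integer(seed))
  pool <- polyclonal_templates(n_clones)
  sim <- simulate_reads(pool$templates, model, n_reads = n_reads,
                        abundances = pool$abundances, n_lanes = 1L,
                        seed = as.integer(seed) + 1L)
  ex <- extract_cdr3(sim$reads, template_flanks(pool$templates[[1]]))
  tables <- lapply(q_cutoffs, function(q)
    build_clone_table(phred_filter(ex$records, q)$records))
  names(tables) <- paste0("q", q_cutoffs)
  culls <- lapply(tables, cull_polyclonal, cutoffs = cutoffs, top_k = top_k)
  rich <- richness_report(tables, rare_cutoff = rare_cutoff)
  manifest <- list(
    mode = "polyclonal_filter", seed = seed, n_clones = n_clones,
    n_reads = nrow(sim$reads), n_accepted = nrow(ex$records),
    n_rejected = nrow(ex$rejects), q_cutoffs = q_cutoffs,
    cutoffs = cutoffs, top_k = top_k)
  out <- list(sim = sim, extraction = ex, tables = tables, culling = culls,
              richness = rich, manifest = manifest)
  if (!is.null(out_dir)) .write_bundle(out, out_dir)
  out
}

## write the machine-readable report bundle: TSVs for tables, JSON for
## summaries, plus a manifest listing every file with its row count
.write_bundle <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  wtsv <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- list(file = basename(path), rows = nrow(df))
  }
  if (!is.null(run$profile)) {
    wtsv(run$profile$summary, "profile_summary")
    wtsv(run$profile$spectrum, "error_spectrum")
  }
  if (!is.null(run$sub_matrix)) wtsv(as.data.frame(run$sub_matrix),
                                     "substitution_matrix")
  if (!is.null(run$lane_cv)) wtsv(run$lane_cv$composite, "lane_cv")
  if (!is.null(run$lane_anova)) wtsv(run$lane_anova$cells, "lane_anova")
  if (!is.null(run$per_nt_rates)) wtsv(run$per_nt_rates, "per_nt_rates")
  if (!is.null(run$complementation)) wtsv(run$complementation,
                                          "complementation")
  if (!is.null(run$richness)) wtsv(run$richness, "richness")
  if (!is.null(run$tables))
    for (nm in names(run$tables))
      wtsv(as.data.frame(run$tables[[nm]]), paste0("clones_", nm))
  if (!is.null(run$culling) && run$manifest$mode == "monoclonal_audit") {
    resid <- data.frame(
      cutoff = as.numeric(names(run$culling)),
      n_culled = vapply(run$culling, function(x) nrow(x$culled), integer(1)),
      residual_error_fraction = vapply(run$culling, function(x)
        x$residual_error_fraction, numeric(1)))
    wtsv(resid, "residual_error")
  }
  manifest <- c(run$manifest, list(files = files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
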