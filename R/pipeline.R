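#' Assemble a pipeline run configuration
#'
#' A run either simulates its input (``simulation`` settings) or reads an
#' existing VCF + popmap + annotation (``input`` paths) — exactly one of
#' the two. Stage toggles select which analysis layers run; every seed and
#' default is echoed into the run's provenance block.
#'
#' @param path optional YAML file with the same fields as the arguments;
#'   explicit arguments override the file.
#' @param input list with \code{vcf}, \code{popmap}, \code{annotation}
#'   paths, or \code{NULL} to simulate.
#' @param simulation list of [simulation_config()] arguments, or
#'   \code{NULL} to read real input.
#' @param stages character vector among \code{"stats"},
#'   \code{"fourgametes"}, \code{"sfs"}, \code{"demography"},
#'   \code{"convert"} (default: all).
#' @param models model ids for the demography stage.
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @param n_perm permutations for the differentiation G-test.
#' @param n_starts,n_genealogies,final_n_genealogies,jackknife_reps
#'   demography-stage settings (see [fit_model()], [jackknife_datasets()]).
#' @param calibration list with \code{comparisons} (data frame of
#'   \code{sites}, \code{substitutions}, \code{tmrca_years}) and
#'   \code{gen_time} (or \code{alpha} and \code{s}), for the convert stage.
#' @param L adjusted surveyed length in bp for unit conversion; when
#'   \code{NULL} it is computed as (total surveyed bp) x (proportion of
#'   SNPs retained after thinning).
#' @param out_dir output directory.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(path = NULL, input = NULL, simulation = NULL,
                       stages = c("stats", "fourgametes", "sfs",
                                  "demography", "convert"),
                       models = c("neutral", "split_mig", "split_no_mig"),
                       seed = 1L, n_perm = 10000, n_starts = 3,
                       n_genealogies = 20000, final_n_genealogies = 100000,
                       jackknife_reps = 10, calibration = NULL, L = NULL,
                       out_dir = tempfile("ucepopgen_run")) {
  cfg <- list(input = input, simulation = simulation, stages = stages,
              models = models, seed = as.integer(seed), n_perm = n_perm,
              n_starts = n_starts, n_genealogies = n_genealogies,
              final_n_genealogies = final_n_genealogies,
              jackknife_reps = jackknife_reps, calibration = calibration,
              L = L, out_dir = out_dir)
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    known <- names(cfg)
    bad <- setdiff(names(file_cfg), known)
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    supplied <- names(as.list(match.call()))[-1]
    for (f in setdiff(names(file_cfg), supplied)) cfg[[f]] <- file_cfg[[f]]
  }
  has_sim <- !is.null(cfg$simulation)
  has_input <- !is.null(cfg$input)
  if (has_sim == has_input)
    stop("exactly one of `input` (real data) or `simulation` must be given")
  bad <- setdiff(cfg$stages, c("stats", "fourgametes", "sfs", "demography",
                               "convert"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if ("demography" %in% cfg$stages && !("sfs" %in% cfg$stages))
    stop("the demography stage requires the sfs stage")
  if ("convert" %in% cfg$stages) {
    if (!("demography" %in% cfg$stages))
      stop("the convert stage requires the demography stage")
    if (is.null(cfg$calibration))
      stop("the convert stage needs a `calibration` block")
  }
  structure(cfg, class = "run_config")
}

stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 101L, stats = 211L, sfs = 307L, demography = 401L,
               jackknife = 503L)
  (cfg$seed * 1009L + offsets[[stage]]) %% 2147483399L
}

write_tsv <- function(df, dir, name) {
  p <- file.path(dir, name)
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

# Run a stage body, relabelling any error with the stage name. The body is
# a promise evaluated in the caller's frame, so its assignments persist
# there; partial outputs written before the failure are retained on disk.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate/read, summary
#' statistics, four-gamete filtering, folded joint-SFS construction,
#' demographic model comparison with jackknife CIs, and unit conversion —
#' writing every intermediate artifact (TSV/VCF/SFS dialect/JSON) under the
#' configured output directory. Rerunning with the same configuration and
#' seed reproduces identical outputs.
#'
#' @param cfg a [run_config()].
#' @return An object of class \code{run_report}: per-stage summary
#'   sections plus a provenance block (configuration echo and hash, seeds,
#'   package version).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  log_msg <- function(...) message("[ucepopgen] ", ...)

  # --- input stage ---------------------------------------------------------
  if (!is.null(cfg$simulation)) with_stage("simulate", {
    sim_args <- cfg$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- stage_seed(cfg, "simulate")
    if (!is.null(sim_args$params) && !inherits(sim_args$params,
                                               "demographic_params"))
      sim_args$params <- do.call(demographic_params, sim_args$params)
    scfg <- do.call(simulation_config, sim_args)
    ds <- generate_dataset(scfg)
    ls <- ds$locus_set
    write_dataset(ds, cfg$out_dir)
    report$simulate <- list(model = scfg$model,
                            n_variable_loci = length(ls$loci),
                            n_invariant_loci =
                              if (is.null(ls$invariant)) 0L
                              else nrow(ls$invariant),
                            n_snps = n_snps(ls), seed = scfg$seed)
    log_msg("simulated ", length(ls$loci), " variable loci (",
            n_snps(ls), " SNPs)")
  }) else with_stage("input", {
    ls <- read_locus_set(cfg$input$vcf, cfg$input$popmap,
                         cfg$input$annotation)
    report$input <- list(n_variable_loci = length(ls$loci),
                         n_invariant_loci = if (is.null(ls$invariant)) 0L
                                            else nrow(ls$invariant),
                         n_snps = n_snps(ls))
    log_msg("read ", length(ls$loci), " variable loci")
  })

  # --- stats ---------------------------------------------------------------
  if ("stats" %in% cfg$stages) with_stage("stats", {
    set.seed(stage_seed(cfg, "stats"))
    div <- divergence_stats(ls)
    fst <- weir_cockerham_fst(ls, "overall")
    fst_locus <- weir_cockerham_fst(ls, "locus")
    perm <- permutation_differentiation_test(ls, n_perm = cfg$n_perm)
    hwe <- hwe_test(ls)
    het <- heterozygosity_summary(ls)
    dapc <- assign_individuals(ls, n_pcs = 4)
    write_tsv(fst_locus, cfg$out_dir, "fst_by_locus.tsv")
    write_tsv(hwe$snp_table, cfg$out_dir, "hwe_by_snp.tsv")
    write_tsv(data.frame(sample = rownames(dapc$posterior),
                         round(dapc$posterior, 6),
                         assigned = dapc$assigned),
              cfg$out_dir, "assignment.tsv")
    report$stats <- list(
      pi_overall = div$pi_overall, pi_by_pop = as.list(div$pi_by_pop),
      dxy = div$dxy, dA = div$dA,
      fst_overall = fst$fst, g_test_p = perm$p_value,
      n_loci_in_hwe = hwe$n_loci_in_hwe, n_loci_out_of_hwe = hwe$n_loci_out,
      ho = as.list(het$ho), he = as.list(het$he),
      bartlett_p = het$bartlett$p,
      paired_t = het$paired_t,
      unique_alleles = as.list(het$unique_alleles),
      diagnosability = dapc$diagnosability)
    log_msg("stats: FST = ", signif(fst$fst, 3),
            ", pi = ", signif(div$pi_overall, 3))
  })

  # --- four-gamete filtering ----------------------------------------------
  if ("fourgametes" %in% cfg$stages) with_stage("fourgametes", {
    fg <- filter_fourgametes(ls)
    write_tsv(fg$report, cfg$out_dir, "fourgametes_report.tsv")
    report$fourgametes <- recombination_summary(fg$report)
    log_msg("four-gamete filter: ",
            report$fourgametes$n_affected, "/", nrow(fg$report),
            " loci affected")
    # downstream SFS analyses use SNPs from the unfiltered set, as the
    # filtered sequences serve sequence-based (not SFS) analyses
  })

  # --- SFS -----------------------------------------------------------------
  if ("sfs" %in% cfg$stages) with_stage("sfs", {
    set.seed(stage_seed(cfg, "sfs"))
    snps <- prepare_snp_matrix(ls, z_policy = "exclude", thinning = "random")
    data_sfs <- build_folded_joint_sfs(snps)
    write_sfs(data_sfs, file.path(cfg$out_dir, "data_sfs.txt"))
    set.seed(stage_seed(cfg, "jackknife"))
    jk <- jackknife_datasets(snps, n_reps = cfg$jackknife_reps)
    report$sfs <- list(n_snps_used = nrow(snps),
                       dropped = attr(snps, "dropped"),
                       n1 = attr(snps, "n1"), n2 = attr(snps, "n2"),
                       jackknife_reps = cfg$jackknife_reps)
    log_msg("SFS built from ", nrow(snps), " one-SNP loci")
  })

  # --- demography ----------------------------------------------------------
  if ("demography" %in% cfg$stages) with_stage("demography", {
    cmp <- compare_models(data_sfs, cfg$models,
                          n_starts = cfg$n_starts,
                          n_genealogies = cfg$n_genealogies,
                          final_n_genealogies = cfg$final_n_genealogies,
                          seed = stage_seed(cfg, "demography"))
    write_tsv(cmp$table, cfg$out_dir, "model_comparison.tsv")
    best_id <- cmp$table$model[1]
    best <- cmp$fits[[best_id]]
    ci <- NULL
    if (length(best$free) > 0) {
      ci <- jackknife_ci(jk$replicates, best_id, best,
                         n_genealogies = cfg$n_genealogies)
      write_tsv(ci, cfg$out_dir, "jackknife_ci.tsv")
    }
    report$demography <- list(ranking = cmp$table, best_model = best_id,
                              best_fit = list(free = as.list(best$free),
                                              theta_hat = best$theta_hat,
                                              loglik = best$loglik,
                                              converged = best$converged),
                              ci = ci)
    log_msg("best model: ", best_id,
            " (log composite likelihood ", round(best$loglik, 2), ")")
  })

  # --- conversion ----------------------------------------------------------
  if ("convert" %in% cfg$stages) with_stage("convert", {
    calib <- cfg$calibration
    cal <- rate_calibration(as.data.frame(calib$comparisons),
                            gen_time = calib$gen_time,
                            alpha = calib$alpha, s = calib$s)
    L <- cfg$L
    if (is.null(L))
      L <- total_surveyed_bp(ls) * nrow(snps) / n_snps(ls)
    p <- best$params
    ci_list <- NULL
    if (!is.null(ci)) {
      ci_list <- lapply(seq_len(nrow(ci)), function(i)
        c(ci$lower[i], ci$upper[i]))
      names(ci_list) <- ci$param
      names(ci_list)[names(ci_list) == "m"] <- "m12"
      if ("m12" %in% names(ci_list) && !("m21" %in% names(ci_list)) &&
          best$model %in% c("split_mig"))
        ci_list$m21 <- ci_list$m12
    }
    bio <- convert_parameters(best$theta_hat, p$nu1, p$nu2, p$T,
                              p$m12, p$m21, cal = cal, L = L, ci = ci_list)
    write_tsv(bio$table, cfg$out_dir, "parameters_bio_units.tsv")
    report$convert <- list(L = L, rate_per_year = cal$rate_per_year,
                           gen_time = cal$gen_time,
                           mu_per_generation = cal$mu_per_generation,
                           nref = bio$nref, n1 = bio$n1, n2 = bio$n2,
                           t_years = bio$t_years,
                           migrants_1 = bio$migrants_1,
                           migrants_2 = bio$migrants_2)
    log_msg("Nref = ", round(bio$nref), ", split time = ",
            round(bio$t_years), " years")
  })

  # --- provenance ----------------------------------------------------------
  cfg_echo <- unclass(cfg)
  cfg_path <- file.path(cfg$out_dir, "config_echo.yaml")
  yaml::write_yaml(cfg_echo, cfg_path)
  report$provenance <- list(
    config = cfg_echo,
    config_hash = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("ucepopgen")))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("ucepopgen run report; sections:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  if (!is.null(x$stats))
    cat("  FST =", signif(x$stats$fst_overall, 3),
        "| pi =", signif(x$stats$pi_overall, 4),
        "| diagnosability =", x$stats$diagnosability, "\n")
  if (!is.null(x$demography))
    cat("  best model:", x$demography$best_model, "\n")
  if (!is.null(x$convert))
    cat("  Nref =", round(x$convert$nref),
        "| T =", round(x$convert$t_years), "years\n")
  invisible(x)
}
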