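#' Default pipeline configuration
#'
#' Nested list of every stage's parameters with the cohort's canonical
#' thresholds: call rate 0.98, variant missingness 5%, HWE P 1e-6,
#' heterozygosity +/- 3 SD, PI_HAT 0.2, boys' minimum last age 12 years,
#' genome-wide significance 5e-8 and nominal 1e-6. Unknown keys in a
#' user configuration are rejected by [validate_config()].
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = "pubgrowth_run",
    simulate = list(
      n = 300L, m = 2000L,
      divergence = c(0.12, 0.12, 0.05, 0.05),
      dirichlet = as.numeric(default_dirichlet),
      generations = 15, spacing_bp = 1e5, missing_rate = 0.002,
      noise_sd = 0.5,
      causal_id = NULL, causal_pv_effect = -2.5,
      theta_apv = -0.73, theta_hapv = -4.3,
      sd_alpha = 4, sd_beta = 0.6, sd_gamma = 0.1,
      schedule = seq(5, 16.5, by = 0.5)
    ),
    qc = list(call_rate = 0.98, miss = 0.05, hwe = 1e-6, het_sd = 3,
              pi_hat = 0.2, boys_min_last_age = 12),
    growth = list(spline_df = 10L, tol = 1e-6, max_iter = 30L),
    ancestry = list(source = "supervised", tol = 1e-4, max_iter = 2000L),
    gwas = list(phenotype = "pv", model = "full", mac_min = 1L,
                gw = 5e-8, nominal = 1e-6)
  )
}

#' Validate and complete a pipeline configuration
#'
#' Merges a (possibly partial) user configuration over the defaults and
#' rejects any key not present in [default_pipeline_config()].
#'
#' @param config Partial configuration list (or path to a YAML file).
#' @return The completed configuration.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- default_pipeline_config()
  check <- function(user, def, path = "") {
    bad <- setdiff(names(user), names(def))
    if (length(bad) > 0) {
      stop("unknown configuration key(s): ",
           paste0(path, bad, collapse = ", "))
    }
    for (nm in names(user)) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        check(user[[nm]], def[[nm]], paste0(path, nm, "."))
      }
    }
  }
  check(config, defaults)
  merged <- utils::modifyList(defaults, config)
  merged$seed <- as.integer(merged$seed)
  merged
}

subset_local_ancestry <- function(la, sample_keep = NULL,
                                  variant_keep = NULL) {
  pick <- function(m, i, j) {
    if (is.null(m)) return(NULL)
    m[i %||% seq_len(nrow(m)), j %||% seq_len(ncol(m)), drop = FALSE]
  }
  structure(list(
    dosage = pick(la$dosage, sample_keep, variant_keep),
    hap1 = pick(la$hap1, sample_keep, variant_keep),
    hap2 = pick(la$hap2, sample_keep, variant_keep),
    labels = la$labels,
    ids = la$ids[sample_keep %||% seq_along(la$ids)],
    native_labels = la$native_labels,
    n_switches = NULL
  ), class = "local_ancestry")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full simulate - QC - growth - ancestry - GWAS pipeline
#'
#' Executes the stages in order into a flat run directory: cohort
#' simulation (VCF, heights TSV, local- and global-ancestry TSVs, truth
#' JSON), quality control (variant, sample and relatedness filters plus
#' the boys' age filter), growth-model fitting and landmark extraction
#' (phenotypes TSV), supervised global-ancestry estimation, and the
#' per-SNP interaction GWAS with significance labels and a Manhattan
#' export. A manifest with MD5 checksums of every artifact is written
#' last; re-running with the same configuration and seed reproduces the
#' checksums.
#'
#' @param config Configuration list or YAML path (see
#'   [default_pipeline_config()]).
#' @param seed Optional seed override.
#' @param outdir Optional output directory override.
#' @return Invisibly, a list with the main in-memory results (`geno`,
#'   `phenotypes`, `ancestry`, `gwas`, `qc_report`, `manifest_path`).
#' @export
run_pipeline <- function(config = list(), seed = NULL, outdir = NULL) {
  cfg <- validate_config(if (is.list(config)) config else config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(cfg$outdir, f)
  sc <- cfg$simulate

  # -- simulate ------------------------------------------------------
  sim <- pipeline_stage("simulate", {
    panel <- simulate_reference_freqs(4, sc$m, sc$divergence,
                                      seed = cfg$seed,
                                      spacing_bp = sc$spacing_bp)
    q <- simulate_admixture(sc$n, sc$dirichlet, seed = cfg$seed + 1L)
    la <- simulate_local_ancestry(q, panel, generations = sc$generations,
                                  seed = cfg$seed + 2L)
    colnames(la$dosage) <- panel$variants$id
    geno <- simulate_genotypes(panel, la, missing_rate = sc$missing_rate,
                               seed = cfg$seed + 3L)
    causal <- NULL
    if (!is.null(sc$causal_id)) {
      cid <- sc$causal_id
      if (identical(cid, "auto")) {
        # pick a variant whose *alternate* allele is low-frequency, like
        # the cohort's headline hits (effects are counted per alt allele)
        ac <- colSums(geno$g, na.rm = TRUE)
        nn <- 2 * colSums(!is.na(geno$g))
        target <- round(0.06 * 2 * sc$n)
        ok <- ac / nn <= 0.5
        cand <- which(ok)[which.min(abs(ac[ok] - target))]
        cid <- geno$variants$id[cand]
      }
      causal <- causal_pv_effect(cid, sc$causal_pv_effect)
    }
    tc <- growth_truth_config(causal = causal, theta_apv = sc$theta_apv,
                              theta_hapv = sc$theta_hapv,
                              sd_alpha = sc$sd_alpha, sd_beta = sc$sd_beta,
                              sd_gamma = sc$sd_gamma)
    gr <- simulate_growth(geno, q, tc, schedule = sc$schedule,
                          noise_sd = sc$noise_sd, seed = cfg$seed + 4L)
    write_cohort_vcf(geno, art("genotypes.vcf"))
    write_heights_tsv(gr$heights, art("heights.tsv"))
    write_local_ancestry_tsv(la, panel$variants$id,
                             art("local_ancestry.tsv"))
    write_ancestry_tsv(q, art("global_ancestry_true.tsv"))
    write_panel_tsv(panel, art("panel.tsv"))
    write_sim_truth_json(gr$truth, art("sim_truth.json"))
    list(panel = panel, q = q, la = la, geno = geno,
         heights = gr$heights, truth = gr$truth)
  })

  # -- qc ------------------------------------------------------------
  qc <- pipeline_stage("qc", {
    reports <- list()
    ba <- boys_age_filter(sim$heights,
                          min_last_age = cfg$qc$boys_min_last_age)
    reports$boys <- ba$report
    vf <- apply_variant_filters(sim$geno, miss_thresh = cfg$qc$miss,
                                hwe_thresh = cfg$qc$hwe)
    reports$variants <- vf$report
    sf <- apply_sample_filters(vf$geno,
                               call_rate_thresh = cfg$qc$call_rate,
                               het_sd = cfg$qc$het_sd)
    reports$samples <- sf$report
    pr <- ibd_prune(sf$geno, pi_hat_thresh = cfg$qc$pi_hat,
                    seed = cfg$seed + 5L)
    reports$ibd <- pr$report
    geno <- pr$geno
    # drop samples removed by the boys' age filter from genotypes too
    keep <- !geno$ids %in% ba$removed_ids
    geno <- subset_samples(geno, keep)
    heights <- dplyr::filter(ba$heights, .data$id %in% geno$ids)
    la <- subset_local_ancestry(
      sim$la,
      sample_keep = match(geno$ids, sim$la$ids),
      variant_keep = match(geno$variants$id, sim$panel$variants$id))
    report <- dplyr::bind_rows(reports)
    readr::write_tsv(report, art("qc_report.tsv"))
    jsonlite::write_json(report, art("qc_report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    list(geno = geno, heights = heights, la = la, report = report)
  })

  # -- growth --------------------------------------------------------
  growth <- pipeline_stage("fit-growth", {
    dp <- derive_phenotypes(qc$heights, spline_df = cfg$growth$spline_df,
                            tol = cfg$growth$tol,
                            max_iter = cfg$growth$max_iter)
    readr::write_tsv(dp$phenotypes, art("phenotypes.tsv"))
    dp
  })

  # -- ancestry ------------------------------------------------------
  anc <- pipeline_stage("ancestry", {
    panel_qc <- read_panel_subset(sim$panel, qc$geno$variants$id)
    q_hat <- if (cfg$ancestry$source == "supervised") {
      supervised_admixture(qc$geno, panel_qc, tol = cfg$ancestry$tol,
                           max_iter = cfg$ancestry$max_iter)
    } else {
      gl <- global_from_local(qc$la)
      tibble::tibble(id = gl$id, Mapuche = gl$native_prop)
    }
    write_ancestry_tsv(q_hat, art("global_ancestry_estimated.tsv"))
    q_hat
  })

  # -- gwas ----------------------------------------------------------
  gw <- pipeline_stage("gwas", {
    phen <- dplyr::filter(growth$phenotypes, .data$id %in% qc$geno$ids)
    keep <- match(phen$id, qc$geno$ids)
    geno_al <- subset_samples(qc$geno, keep)
    la_al <- subset_local_ancestry(qc$la, sample_keep = keep)
    spec <- model_spec(cfg$gwas$model)
    res <- run_gwas(phen, geno_al,
                    la = if (spec$model == "full") la_al else NULL,
                    q = anc, phenotype = cfg$gwas$phenotype, spec = spec,
                    mac_min = cfg$gwas$mac_min)
    res <- classify_significance(res, gw = cfg$gwas$gw,
                                 nominal = cfg$gwas$nominal)
    readr::write_tsv(res, art("gwas_results.tsv"))
    readr::write_tsv(manhattan_export(res), art("manhattan.tsv"))
    res
  })

  # -- manifest ------------------------------------------------------
  manifest <- pipeline_stage("report", {
    files <- sort(list.files(cfg$outdir,
                             pattern = "\\.(vcf|tsv|json)$"))
    sums <- tools::md5sum(file.path(cfg$outdir, files))
    man <- list(seed = cfg$seed,
                files = as.list(setNames(unname(sums), files)))
    jsonlite::write_json(man, art("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    man
  })

  invisible(list(geno = qc$geno, phenotypes = growth$phenotypes,
                 ancestry = anc, gwas = gw, qc_report = qc$report,
                 truth = sim$truth, fits = growth$fits,
                 manifest_path = art("manifest.json"),
                 config = cfg))
}

read_panel_subset <- function(panel, variant_ids) {
  j <- match(variant_ids, panel$variants$id)
  structure(list(K = panel$K, labels = panel$labels,
                 freqs = panel$freqs[, j, drop = FALSE],
                 variants = panel$variants[j, , drop = FALSE],
                 genetic_pos = panel$genetic_pos[j],
                 ancestral = panel$ancestral[j]),
            class = "reference_panel")
}
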