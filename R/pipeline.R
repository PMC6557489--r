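#' Run a configured analysis stage
#'
#' Single entry point wiring the package's stages from a YAML
#' configuration file.  The config declares a `stage` (one of `scan`,
#' `mutate`, `predict`, `normalize`, `foldchange`, `qpcr`, `simulate`),
#' its input files, parameters, and an `out_dir`; every source of
#' randomness flows from a declared `seed`.  Results are written as TSV
#' (or FASTA for `mutate`) next to a machine-readable run manifest
#' (parameters, input digests, seed, package version, timestamp).
#'
#' Typical shell use: `Rscript -e 'crmkit::run_pipeline("config.yml")'`.
#'
#' @param config_path YAML configuration file.
#' @return invisibly, `list(status = 0, manifest = <path>, outputs =
#'   <paths>)`; errors abort with a message naming the offending field.
#' @export
run_pipeline <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  need <- function(field, type = NULL) {
    v <- cfg[[field]]
    if (is.null(v))
      stop("config is missing field `", field, "`",
           if (!is.null(type)) paste0(" (expected ", type, ")"))
    v
  }
  stage <- need("stage", "character")
  out_dir <- need("out_dir", "directory path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  outputs <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  q_min <- cfg$q_min %||% 0.01

  if (stage == "scan") {
    crms <- read_crm_fasta(need("fasta", "FASTA path"))
    mats <- lapply(need("matrices", "list of matrix paths"),
                   read_count_matrix)
    inputs <- c(cfg$fasta, unlist(cfg$matrices))
    sites <- do.call(rbind, lapply(crms, function(crm) {
      s <- scan_sites(crm, mats, q_min)
      if (nrow(s)) cbind(construct = crm$id, s) else NULL
    }))
    wr(sites[, c("construct", "start", "end", "strand", "tf", "q")],
       "sites.tsv")
  } else if (stage == "mutate") {
    crms <- read_crm_fasta(need("fasta", "FASTA path"))
    mats <- lapply(need("matrices", "list of matrix paths"),
                   read_count_matrix)
    inputs <- c(cfg$fasta, unlist(cfg$matrices))
    crm <- crms[[need("crm_id", "character")]]
    if (is.null(crm)) stop("crm_id not found in FASTA")
    sites <- scan_sites(crm, mats, q_min)
    tgt <- sites[sites$tf == need("target_tf", "character") &
                   sites$start == need("target_start", "integer"), ,
                 drop = FALSE]
    if (nrow(tgt) == 0L) stop("target site not found in the scan")
    plan <- design_site_mutation(crm, tgt[1L, ], mats, q_min)
    mut <- apply_mutation_plan(crm, plan)
    mut$id <- paste0(crm$id, "_mut")
    p <- file.path(out_dir, "mutant.fa")
    write_crm_fasta(mut, p)
    outputs <- c(outputs, p)
    wr(plan$edits, "edits.tsv")
  } else if (stage == "predict") {
    crms <- read_crm_fasta(need("fasta", "FASTA path"))
    mats <- lapply(need("matrices", "list of matrix paths"),
                   read_count_matrix)
    spec <- read_thermo_spec(need("model", "model spec path"))
    inputs <- c(cfg$fasta, unlist(cfg$matrices), cfg$model)
    roles <- vapply(crms, `[[`, character(1), "role")
    prom <- crms[[which(roles == "promoter")[1L]]]
    distals <- crms[roles != "promoter"]
    folds <- predict_mutant_series(prom, distals, spec, mats,
                                   spacer_bp = cfg$spacer_bp %||% 2000,
                                   q_min = q_min)
    wr(folds, "predicted_folds.tsv")
  } else if (stage == "normalize") {
    tab <- load_luminescence_table(need("luminescence", "CSV path"))
    inputs <- cfg$luminescence
    config <- do.call(robust_config, cfg$robust %||% list())
    if (isTRUE(cfg$ci) && is.null(cfg$seed))
      stop("config is missing field `seed` (integer, required when ",
           "ci: true)")
    groups <- split(tab, list(tab$construct, tab$condition), drop = TRUE)
    rows <- lapply(groups, function(g) {
      fit <- eiv_slope(g$renilla, g$firefly, config)
      ci <- c(NA_real_, NA_real_)
      if (isTRUE(cfg$ci))
        ci <- bootstrap_ci(g$renilla, g$firefly, config,
                           seed = cfg$seed, fit = fit)
      data.frame(construct = g$construct[1L], condition = g$condition[1L],
                 beta = fit$beta, scale = fit$scale, n = fit$n,
                 ci_low = ci[1L], ci_high = ci[2L],
                 stringsAsFactors = FALSE)
    })
    wr(do.call(rbind, rows), "slopes.tsv")
  } else if (stage == "foldchange") {
    tab <- load_luminescence_table(need("luminescence", "CSV path"))
    inputs <- cfg$luminescence
    seed <- need("seed", "integer")
    config <- do.call(robust_config, cfg$robust %||% list())
    mode <- cfg$mode %||% "vs_same_condition_promoter"
    groups <- unique(tab[tab$construct != (cfg$reference %||% "0"),
                         c("construct", "condition")])
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      fold_change(tab, groups$construct[i], groups$condition[i], mode,
                  config, seed = seed + i,
                  reference_construct = cfg$reference %||% "0")
    })
    folds <- do.call(rbind, rows)
    cls <- classify_crm(folds)
    folds$class <- cls$class[match(folds$construct, cls$construct)]
    wr(folds, "foldchanges.tsv")
  } else if (stage == "qpcr") {
    rec <- read.csv(need("qpcr", "CSV path"), stringsAsFactors = FALSE)
    inputs <- cfg$qpcr
    wr(qpcr_relative_expression(rec), "relative_expression.tsv")
  } else if (stage == "simulate") {
    seed <- need("seed", "integer")
    sim <- simulate_luminescence(
      true_beta = need("true_beta", "number"),
      n = cfg$n %||% 10,
      transfection_sdlog = cfg$transfection_sdlog %||% 0.35,
      measurement_cv = cfg$measurement_cv %||% 0.1,
      outlier_frac = cfg$outlier_frac %||% 0,
      outlier_scale = cfg$outlier_scale %||% 10, seed = seed)
    p <- file.path(out_dir, "luminescence.csv")
    write.csv(sim$table, p, row.names = FALSE)
    outputs <- c(outputs, p)
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                         digits = NA)
    outputs <- c(outputs, truth_path)
  } else {
    stop("unknown stage `", stage, "`")
  }

  manifest <- list(
    subcommand = stage,
    parameters = cfg,
    input_digests = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    seed = cfg$seed,
    package_version = as.character(packageVersion("crmkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(list(status = 0L, manifest = manifest_path,
                 outputs = outputs))
}
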