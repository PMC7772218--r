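#' Default pipeline configuration
#'
#' @param vcf,metadata,phenotypes input paths (`phenotypes` optional).
#' @param out_dir output directory.
#' @param ... overrides of the remaining fields (filter thresholds,
#'   subgroup `pairs`, ROD `steps`, permutation `R`, `seed`, ancestry
#'   `k_min`/`k_max`/`reps`, `ld_bin_bp`/`ld_max_bp`, `traits`, `fdr`).
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf, metadata, phenotypes = NULL, out_dir, ...) {
  cfg <- list(vcf = vcf, metadata = metadata, phenotypes = phenotypes,
              out_dir = out_dir,
              max_missing = 0.30, min_maf = 0.05,
              pairs = NULL,            # default: all subgroup pairs
              steps = names(ROD_STEPS),
              permutations = 1000L, seed = 17L,
              k_min = 2L, k_max = 10L, reps = 5L,
              ld_bin_bp = 10000, ld_max_bp = 500000,
              traits = NULL,           # default: all traits present
              fdr = 0.1, n_pcs = 10L,
              gwas_subsets = NULL)     # e.g. list(fruit_weight = "NS")
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  v <- yaml::read_yaml(path)
  req <- c("vcf", "metadata", "out_dir")
  if (!all(req %in% names(v)))
    stop("config must define: ", paste(req, collapse = ", "))
  do.call(run_config, v)
}

stage_log <- function(stage, ...) {
  message(format(Sys.time(), "[%H:%M:%S] "), "[", stage, "] ", ...)
}

run_stage <- function(stage, expr) {
  stage_log(stage, "start")
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates filter -> diversity -> F_ST / ROD -> LD -> structure ->
#' GBLUP -> GWAS from one configuration, writing per-stage TSV/JSON
#' artifacts under `out_dir/<stage>/` and a machine-readable manifest
#' (package version, seeds, input checksums, every output path).
#' Phenotype-dependent stages are skipped with a logged notice when no
#' phenotype table is configured. Deterministic given the config seed.
#'
#' @param config a [run_config()], or a path to a YAML file.
#' @return invisible list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(stage, name, writer) {
    d <- file.path(out, stage)
    dir.create(d, showWarnings = FALSE)
    path <- file.path(d, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  write_json_file <- function(x, path)
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, na = "null"), path)

  ## -- filter ------------------------------------------------------------
  res <- list()
  res$input <- run_stage("filter", {
    inp <- read_vcf(cfg$vcf, cfg$metadata)
    flt <- filter_markers(inp$genotypes, cfg$max_missing, cfg$min_maf)
    stage_log("filter", flt$report$n_retained, " of ",
              flt$report$n_input_snps, " markers retained")
    emit("filter", "gmat.tsv", function(p) write_matrix(flt$genotypes, p))
    emit("filter", "filter_report.json", function(p)
      write_json_file(unclass(flt$report), p))
    list(G = flt$genotypes, meta = inp$metadata, report = flt$report)
  })
  G <- res$input$G; meta <- res$input$meta
  subgroups <- unique(meta$subgroup)
  pairs <- cfg$pairs %||% utils::combn(subgroups, 2, simplify = FALSE)

  ## -- diversity ----------------------------------------------------------
  res$diversity <- run_stage("diversity", {
    fr <- subgroup_freqs(G, meta)
    emit("diversity", "freqs.tsv", function(p) write_tsv(fr, p))
    poly <- lapply(subgroups, function(s) polymorphic_fraction(fr, s))
    names(poly) <- subgroups
    emit("diversity", "polymorphic.json", function(p) write_json_file(poly, p))
    jm <- lapply(pairs, function(pr) {
      j <- joint_maf(fr, pr[1], pr[2])
      emit("diversity", paste0("joint_maf_", pr[1], "_", pr[2], ".tsv"),
           function(p) write_tsv(as.data.frame(j$table), p))
      j
    })
    list(freqs = fr, polymorphic = poly, joint_maf = jm)
  })

  ## -- selection scan ------------------------------------------------------
  res$fst <- run_stage("fst", {
    scans <- lapply(seq_along(pairs), function(i) {
      pr <- pairs[[i]]
      sc <- fst_permutation_threshold(G, meta, pr, R = cfg$permutations,
                                      seed = derive_seed(cfg$seed, 100 + i))
      emit("fst", paste0("fst_", pr[1], "_", pr[2], ".tsv"), function(p)
        write_tsv(cbind(sc$markers, theta = unname(sc$theta)), p))
      emit("fst", paste0("fst_", pr[1], "_", pr[2], "_summary.json"),
           function(p) write_json_file(
             list(pair = pr, mean_fst = sc$mean_fst, max_fst = sc$max_fst,
                  ratio_of_sums = sc$fst_ratio_of_sums,
                  perm_threshold_p95 = sc$perm_threshold_p95,
                  n_significant = sc$n_significant, R = sc$R,
                  seed = sc$seed), p))
      stage_log("fst", pr[1], " vs ", pr[2], ": mean ",
                fmt_num(sc$mean_fst), ", p95 ",
                fmt_num(sc$perm_threshold_p95))
      sc
    })
    names(scans) <- vapply(pairs, paste, "", collapse = "_")
    scans
  })

  res$rod <- run_stage("rod", {
    steps <- cfg$steps[vapply(cfg$steps, function(s) {
      pr <- ROD_STEPS[[s]]
      all(pr %in% subgroups)
    }, TRUE)]
    scans <- lapply(steps, function(s) {
      rs <- rod_scan(G, meta, step = s)
      emit("rod", paste0("rod_", s, ".tsv"), function(p)
        write_tsv(rs$table, p))
      emit("rod", paste0("rod_", s, "_summary.json"), function(p)
        write_json_file(list(step = s, pair = as.list(rs$pair),
                             bin_counts = as.list(rs$bin_counts)), p))
      rs
    })
    names(scans) <- steps
    scans
  })

  ## -- LD -------------------------------------------------------------------
  res$ld <- run_stage("ld", {
    curves <- lapply(subgroups, function(s) {
      lc <- ld_decay(G, meta, s, bin_bp = cfg$ld_bin_bp,
                     max_bp = cfg$ld_max_bp)
      emit("ld", paste0("ld_", s, ".tsv"), function(p)
        write_tsv(lc$curve, p))
      emit("ld", paste0("ld_", s, "_summary.json"), function(p)
        write_json_file(list(subgroup = s, half_decay_bp = lc$half_decay_bp,
                             n_pairs = lc$n_pairs_total), p))
      lc
    })
    names(curves) <- subgroups
    curves
  })

  ## -- structure -------------------------------------------------------------
  res$structure <- run_stage("structure", {
    pca <- pca_genotypes(G, n_comp = cfg$n_pcs)
    emit("structure", "pca_scores.tsv", function(p)
      write_tsv(data.frame(accession_id = rownames(G$dosages), pca$scores), p))
    emit("structure", "pca_variance.tsv", function(p)
      write_tsv(data.frame(component = seq_along(pca$explained),
                           explained = pca$explained), p))
    wt <- ward_tree(G)
    emit("structure", "tree.nwk", function(p) writeLines(wt$newick, p))
    ks <- seq(cfg$k_min, min(cfg$k_max, nrow(G$dosages) - 1L))
    fits <- lapply(seq_along(ks), function(i)
      snmf_fit(G, ks[i], n_replicates = cfg$reps,
               seed = derive_seed(cfg$seed, 200 + i)))
    sel <- select_k(fits)
    emit("structure", "ce_by_k.tsv", function(p) write_tsv(sel$table, p))
    best <- fits[[which(ks == sel$K)]]
    for (f in fits)
      emit("structure", paste0("q_matrix_K", f$K, ".tsv"), function(p)
        write_tsv(data.frame(accession_id = rownames(f$Q), f$Q), p))
    stage_log("structure", "selected K = ", sel$K)
    list(pca = pca, tree = wt, fits = fits, selected_k = sel, best = best)
  })

  ## -- phenotype stages -------------------------------------------------------
  if (is.null(cfg$phenotypes)) {
    stage_log("blup", "no phenotype table configured; skipping BLUP and GWAS")
  } else {
    pheno <- read_tsv(cfg$phenotypes)
    traits <- cfg$traits %||% unique(pheno$trait)
    K <- vanraden_kinship(G)

    res$blup <- run_stage("blup", {
      fits <- lapply(traits, function(tr) fit_gblup(pheno, K, tr))
      names(fits) <- traits
      for (tr in traits)
        emit("blup", paste0("blups_", tr, ".tsv"), function(p)
          write_tsv(fits[[tr]]$blups, p))
      emit("blup", "varcomp.json", function(p)
        write_json_file(lapply(fits, function(f) as.list(f$varcomp)), p))
      cmp <- lapply(fits, function(f) subgroup_compare(f, meta))
      emit("blup", "comparisons.tsv", function(p)
        write_tsv(do.call(rbind, lapply(traits, function(tr)
          cbind(trait = tr, cmp[[tr]]$descriptives,
                omnibus_p = cmp[[tr]]$omnibus_p))), p))
      wide <- Reduce(function(a, b) merge(a, b, by = "accession_id"),
                     lapply(traits, function(tr)
                       stats::setNames(fits[[tr]]$blups, c("accession_id", tr))))
      rownames(wide) <- wide$accession_id
      cors <- trait_correlations(wide[, -1, drop = FALSE])
      emit("blup", "trait_correlations.tsv", function(p)
        write_tsv(as.data.frame(cors$r), p))
      list(fits = fits, comparisons = cmp, correlations = cors, wide = wide)
    })

    res$gwas <- run_stage("gwas", {
      pca <- res$structure$pca
      Q <- res$structure$best$Q
      covars <- cbind(pca$scores[, seq_len(min(cfg$n_pcs, ncol(pca$scores))),
                                 drop = FALSE],
                      Q[, -ncol(Q), drop = FALSE])
      rownames(covars) <- rownames(G$dosages)
      scans <- list()
      for (tr in traits) {
        yv <- stats::setNames(res$blup$fits[[tr]]$blups$blup,
                              res$blup$fits[[tr]]$blups$accession_id)
        sc <- tryCatch(
          mlm_scan(G, yv, covariates = covars, K = K, alpha = cfg$fdr),
          error = function(e) {
            stage_log("gwas", tr, ": skipped (", conditionMessage(e), ")")
            NULL
          })
        if (is.null(sc)) next
        scans[[paste0(tr, "_all")]] <- sc
        emit("gwas", paste0("gwas_", tr, "_all.tsv"), function(p)
          write_tsv(sc$table, p))
        sub <- cfg$gwas_subsets[[tr]]
        if (!is.null(sub)) {
          ids <- meta$accession_id[meta$subgroup == sub]
          scs <- tryCatch(
            mlm_scan(G, yv, covariates = covars, K = K, subset = ids,
                     alpha = cfg$fdr),
            error = function(e) {
              stage_log("gwas", tr, "/", sub, ": skipped (",
                        conditionMessage(e), ")")
              NULL
            })
          if (!is.null(scs)) {
            scans[[paste0(tr, "_", sub)]] <- scs
            emit("gwas", paste0("gwas_", tr, "_", sub, ".tsv"), function(p)
              write_tsv(scs$table, p))
          }
        }
      }
      scans
    })
  }

  ## -- manifest ---------------------------------------------------------------
  inputs <- c(cfg$vcf, cfg$metadata, cfg$phenotypes)
  manifest <- list(
    package = "bogdiv",
    version = as.character(utils::packageVersion("bogdiv")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = unclass(cfg)[setdiff(names(cfg), "pairs")],
    input_md5 = as.list(tools::md5sum(inputs)),
    outputs = outputs,
    output_md5 = as.list(tools::md5sum(outputs)))
  manifest_path <- file.path(out, "manifest.json")
  write_json_file(manifest, manifest_path)
  stage_log("done", "manifest at ", manifest_path)
  res$manifest <- manifest
  invisible(res)
}
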