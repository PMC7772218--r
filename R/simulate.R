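#' Scenario configuration for the domestication simulator
#'
#' Defaults mirror the cranberry diversity panel: stage sizes 121 wild
#' (WLD), 111 first-generation native selections (NS), 26 cultivars bred
#' from 7 founders (CLT1) and 104 advanced selections tracing to 8
#' grandparents (CLT2); 12 chromosomes with ~25 kb mean marker spacing;
#' intra-chromosomal LD decaying on a d0 = 30 kb scale; wild substructure
#' as Balding-Nichols demes; a polygenic + major-QTL trait architecture
#' with spatial field trends; and ~10% missing genotype calls. Any field
#' can be overridden.
#'
#' @param ... named overrides of the defaults listed below.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(...) {
  cfg <- list(
    n_wld = 121L, n_ns = 111L, n_clt1 = 26L, n_clt2 = 104L,
    n_markers = 2400L, n_chrom = 12L,
    marker_spacing_bp = 25000,
    maf_beta = c(0.5, 0.5),        # shape of the ancestral frequency law
    n_demes = 4L, f_demes = 0.03,  # wild substructure (Balding-Nichols F)
    d0_bp = 30000,                 # adjacent-locus LD decay scale
    recomb_rate = 1e-8,            # per bp (1 cM/Mb)
    n_founders_stage2 = 7L,
    n_grandparents_stage3 = 8L,
    sel_fraction = 0.5,            # truncation fraction at each step
    selection = TRUE,
    degenerate_bottleneck = FALSE, # CLT1 from a single doubled haplotype
    n_polygenes = 300L,
    traits = data.frame(
      trait = c("yield", "fruit_weight", "fruit_rot", "tacy", "brix", "acids"),
      mean  = c(125.77, 1.72, 14.49, 20.01, 9.38, 2.18),
      gsd   = c(60, 0.4, 8, 7, 0.5, 0.18),
      h2    = c(0.4, 0.5, 0.2, 0.35, 0.3, 0.3),
      stringsAsFactors = FALSE),
    qtl = data.frame(              # major QTL on the selected traits
      trait = c("fruit_weight", "yield"),
      effect = c(0.5, 40),         # per alt allele, trait units
      stringsAsFactors = FALSE),
    selection_traits = c("fruit_weight", "yield"),
    years = 3L,
    year_frac = 0.2, spatial_frac = 0.2,  # shares of environmental variance
    missing_rate = 0.10)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$n_wld > 0, cfg$n_ns > 0, cfg$n_clt1 > 0, cfg$n_clt2 > 0,
            cfg$f_demes >= 0, cfg$f_demes < 1, cfg$d0_bp > 0,
            all(cfg$traits$h2 >= 0 & cfg$traits$h2 <= 1),
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$n_founders_stage2 <= cfg$n_ns,
            cfg$sel_fraction > 0, cfg$sel_fraction <= 1)
  class(cfg) <- "scenario_config"
  cfg
}

# marker map: n_markers spread over n_chrom chromosomes, positions drawn
# uniformly and sorted; mean gap ~ marker_spacing_bp
make_marker_map <- function(cfg) {
  per <- rep(cfg$n_markers %/% cfg$n_chrom, cfg$n_chrom)
  extra <- cfg$n_markers %% cfg$n_chrom
  if (extra) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  bases <- c("A", "C", "G", "T")
  mk <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(ch) {
    len <- per[ch] * cfg$marker_spacing_bp
    pos <- sort(sample.int(len, per[ch]))
    data.frame(chrom = sprintf("chr%02d", ch), pos = pos,
               stringsAsFactors = FALSE)
  }))
  mk$id <- paste0(mk$chrom, "_", mk$pos)
  mk$ref <- sample(bases, nrow(mk), replace = TRUE)
  mk$alt <- vapply(mk$ref, function(r) sample(setdiff(bases, r), 1L), "")
  mk[c("id", "chrom", "pos", "ref", "alt")]
}

# first-order Markov haplotypes: marginal frequencies f, adjacent-locus
# correlation exp(-d/d0) within chromosomes. Returns n_hap x L 0/1 matrix.
markov_haplotypes <- function(n_hap, f, chrom, pos, d0) {
  L <- length(f)
  H <- matrix(0L, n_hap, L)
  H[, 1] <- stats::rbinom(n_hap, 1L, f[1])
  for (l in seq_len(L)[-1]) {
    if (chrom[l] != chrom[l - 1L]) {
      H[, l] <- stats::rbinom(n_hap, 1L, f[l])
      next
    }
    rho <- exp(-(pos[l] - pos[l - 1L]) / d0)
    f0 <- f[l - 1L]; f1 <- f[l]
    # cap at the maximum correlation a bivariate Bernoulli with these
    # marginals admits, so the chain preserves marginal frequencies exactly
    if (f0 > 0 && f0 < 1 && f1 > 0 && f1 < 1) {
      odds <- sqrt((f0 * (1 - f1)) / ((1 - f0) * f1))
      rho <- min(rho, odds, 1 / odds)
    }
    cv <- rho * sqrt(f0 * (1 - f0) * f1 * (1 - f1))
    p_given1 <- if (f0 > 0) min(max(f1 + cv / f0, 0), 1) else f1
    p_given0 <- if (f0 < 1) min(max(f1 - cv / (1 - f0), 0), 1) else f1
    pr <- ifelse(H[, l - 1L] == 1L, p_given1, p_given0)
    H[, l] <- stats::rbinom(n_hap, 1L, pr)
  }
  H
}

# one gamete from an individual's two haplotypes, with crossovers as a
# Markov switch process along each chromosome
meiosis <- function(hap1, hap2, chrom, pos, recomb_rate) {
  L <- length(hap1)
  src <- integer(L)
  src[1] <- sample(1:2, 1L)
  r <- 0.5 * (1 - exp(-2 * recomb_rate * diff(pos)))
  r[chrom[-1] != chrom[-L]] <- 0.5     # chromosomes assort independently
  sw <- stats::rbinom(L - 1L, 1L, r)
  src[-1] <- src[1]
  if (any(sw == 1L)) {
    flips <- cumsum(c(0L, sw)) %% 2L
    src <- ifelse(flips == 1L, 3L - src[1], src[1])
  }
  ifelse(src == 1L, hap1, hap2)
}

cross <- function(p1, p2, chrom, pos, recomb_rate) {
  list(meiosis(p1[[1]], p1[[2]], chrom, pos, recomb_rate),
       meiosis(p2[[1]], p2[[2]], chrom, pos, recomb_rate))
}

#' Simulate a domestication diversity panel with known ground truth
#'
#' Generates genotypes, stage metadata, multi-year spatially structured
#' phenotypes and a truth record under a four-stage nested-bottleneck
#' scenario: wild demes (Balding-Nichols differentiation, Markov-chain LD)
#' -> truncation-selected first-generation selections (NS) -> cultivars
#' bred in two generations from a small founder set (CLT1) -> advanced
#' selections constrained to a small grandparent set (CLT2). All
#' randomness derives from `seed`.
#'
#' @param config a [scenario_config()].
#' @param seed master seed (integer).
#' @return list of class `sim_panel`: `genotypes` ([geno_matrix()], with
#'   missing calls masked at the configured rate), `metadata`,
#'   `phenotypes` (long data frame: accession_id, trait, value, year, row,
#'   col), `truth` (ancestral and per-stage allele frequencies, founder /
#'   grandparent ids, QTL effects, true breeding values, spatial field,
#'   deme assignment, complete unmasked dosages).
#' @export
simulate_panel <- function(config = scenario_config(), seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  with_seed(seed, {
    mk <- make_marker_map(cfg)
    L <- nrow(mk)
    p_anc <- 0.05 + 0.90 * stats::rbeta(L, cfg$maf_beta[1], cfg$maf_beta[2])

    # Balding-Nichols deme frequencies
    Fd <- cfg$f_demes
    deme_freq <- lapply(seq_len(cfg$n_demes), function(d) {
      if (Fd == 0) return(p_anc)
      stats::rbeta(L, p_anc * (1 - Fd) / Fd, (1 - p_anc) * (1 - Fd) / Fd)
    })

    draw_wild <- function(n) {
      deme <- rep_len(seq_len(cfg$n_demes), n)
      haps <- lapply(seq_len(cfg$n_demes), function(d) {
        nh <- 2L * sum(deme == d)
        if (!nh) return(NULL)
        markov_haplotypes(nh, deme_freq[[d]], mk$chrom, mk$pos, cfg$d0_bp)
      })
      out <- vector("list", n)
      used <- integer(cfg$n_demes)
      for (i in seq_len(n)) {
        d <- deme[i]
        out[[i]] <- list(haps[[d]][used[d] + 1L, ], haps[[d]][used[d] + 2L, ])
        used[d] <- used[d] + 2L
      }
      list(ind = out, deme = deme)
    }

    dosage_of <- function(ind) ind[[1]] + ind[[2]]

    # trait effect machinery: sparse polygenic background + listed QTL,
    # scaled on the wild base population so sd(BV) = gsd per trait
    wld <- draw_wild(cfg$n_wld)
    wild_dos <- t(vapply(wld$ind, dosage_of, integer(L)))

    traits <- cfg$traits
    beta <- matrix(0, L, nrow(traits), dimnames = list(NULL, traits$trait))
    qtl_rows <- list()
    for (tix in seq_len(nrow(traits))) {
      tr <- traits$trait[tix]
      poly_idx <- sample.int(L, min(cfg$n_polygenes, L))
      b <- numeric(L)
      b[poly_idx] <- stats::rnorm(length(poly_idx))
      bv0 <- as.numeric(wild_dos %*% b)
      if (stats::sd(bv0) > 0) b <- b * (traits$gsd[tix] / stats::sd(bv0))
      qtl_t <- cfg$qtl[cfg$qtl$trait == tr, , drop = FALSE]
      if (nrow(qtl_t)) {
        # place QTL at intermediate-frequency loci so they segregate
        cand <- which(p_anc > 0.3 & p_anc < 0.7)
        qidx <- sample(cand, nrow(qtl_t))
        b[qidx] <- b[qidx] + qtl_t$effect
        qtl_rows[[tr]] <- data.frame(trait = tr, marker = mk$id[qidx],
                                     index = qidx, effect = qtl_t$effect)
      }
      beta[, tix] <- b
    }
    qtl_table <- if (length(qtl_rows)) do.call(rbind, c(qtl_rows,
                                                        make.row.names = FALSE))
                 else NULL

    sel_score <- function(dos) {
      bv <- dos %*% beta[, cfg$selection_traits, drop = FALSE]
      z <- scale(bv)
      rowSums(z) + stats::rnorm(nrow(dos))   # selection accuracy < 1
    }

    select_top <- function(pool, n_keep) {
      dos <- t(vapply(pool, dosage_of, integer(L)))
      sc <- if (cfg$selection) sel_score(dos) else stats::rnorm(length(pool))
      pool[order(sc, decreasing = TRUE)[seq_len(n_keep)]]
    }

    # NS: truncation selection from an oversampled wild pool
    ns_pool <- draw_wild(ceiling(cfg$n_ns / cfg$sel_fraction))
    ns <- select_top(ns_pool$ind, cfg$n_ns)

    # CLT1: two generations of crosses among the stage-2 founders
    founders <- ns[seq_len(cfg$n_founders_stage2)]
    if (cfg$degenerate_bottleneck) {
      hap <- meiosis(founders[[1]][[1]], founders[[1]][[2]],
                     mk$chrom, mk$pos, cfg$recomb_rate)
      clt1 <- replicate(cfg$n_clt1, list(hap, hap), simplify = FALSE)
    } else {
      n_f1 <- max(20L, 2L * cfg$n_founders_stage2)
      f1 <- lapply(seq_len(n_f1), function(i) {
        pr <- sample(seq_along(founders), 2L, replace = FALSE)
        cross(founders[[pr[1]]], founders[[pr[2]]], mk$chrom, mk$pos,
              cfg$recomb_rate)
      })
      pool1 <- lapply(seq_len(ceiling(cfg$n_clt1 / cfg$sel_fraction)),
                      function(i) {
        pr <- sample(seq_along(f1), 2L, replace = FALSE)
        cross(f1[[pr[1]]], f1[[pr[2]]], mk$chrom, mk$pos, cfg$recomb_rate)
      })
      clt1 <- select_top(pool1, cfg$n_clt1)
    }

    # CLT2: CLT1 x CLT1 and CLT1 x NS crosses; the extra NS parent is the
    # grandparent beyond the stage-2 founders
    extra_gp_idx <- cfg$n_founders_stage2 + 1L
    extra_gp <- ns[[min(extra_gp_idx, length(ns))]]
    pool2 <- lapply(seq_len(ceiling(cfg$n_clt2 / cfg$sel_fraction)),
                    function(i) {
      a <- clt1[[sample.int(length(clt1), 1L)]]
      b <- if (stats::runif(1) < 0.5 && !cfg$degenerate_bottleneck)
        extra_gp else clt1[[sample.int(length(clt1), 1L)]]
      cross(a, b, mk$chrom, mk$pos, cfg$recomb_rate)
    })
    clt2 <- select_top(pool2, cfg$n_clt2)

    # assemble panel
    stages <- list(WLD = wld$ind, NS = ns, CLT1 = clt1, CLT2 = clt2)
    ids <- unlist(lapply(names(stages), function(s)
      sprintf("%s_%03d", s, seq_along(stages[[s]]))))
    dos_full <- do.call(rbind, lapply(stages, function(st)
      t(vapply(st, dosage_of, integer(L)))))
    rownames(dos_full) <- ids
    origin <- c(paste0("deme", wld$deme),
                rep("native_selection", length(ns)),
                rep("founder_cross", length(clt1)),
                rep("advanced_cross", length(clt2)))
    meta <- data.frame(accession_id = ids,
                       subgroup = rep(names(stages),
                                      vapply(stages, length, 0L)),
                       origin = origin, stringsAsFactors = FALSE)

    stage_freq <- vapply(names(stages), function(s)
      colMeans(dos_full[meta$subgroup == s, , drop = FALSE]) / 2,
      numeric(L))

    bv <- dos_full %*% beta
    bv <- sweep(bv, 2L, colMeans(bv))     # centred true breeding values

    # phenotypes: accession x year records on a field grid with a smooth
    # spatial surface, year effects, and residual noise set by h2
    n <- nrow(dos_full)
    side <- ceiling(sqrt(n))
    slots <- sample.int(side * side, n)
    frow <- (slots - 1L) %/% side + 1L
    fcol <- (slots - 1L) %% side + 1L
    surf <- smooth_surface(side)
    ph <- list()
    for (tix in seq_len(nrow(traits))) {
      tr <- traits$trait[tix]
      h2 <- traits$h2[tix]
      # environmental variance calibrated to the realized panel-wide BV
      # variance (QTL included), so h2 is exact on the panel scale
      v_bv <- max(stats::var(bv[, tix]), 1e-8)
      env_var <- if (h2 > 0) v_bv * (1 - h2) / h2 else v_bv
      year_sd <- sqrt(cfg$year_frac * env_var)
      spat_sd <- sqrt(cfg$spatial_frac * env_var)
      res_sd <- sqrt(max(env_var * (1 - cfg$year_frac - cfg$spatial_frac),
                         1e-8))
      yeff <- stats::rnorm(cfg$years, 0, year_sd)
      spat <- spat_sd * surf[cbind(frow, fcol)]
      for (y in seq_len(cfg$years)) {
        ph[[length(ph) + 1L]] <- data.frame(
          accession_id = ids, trait = tr,
          value = traits$mean[tix] + bv[, tix] + yeff[y] + spat +
            stats::rnorm(n, 0, res_sd),
          year = 2005L + y, row = frow, col = fcol,
          stringsAsFactors = FALSE)
      }
    }
    phenotypes <- do.call(rbind, ph)
    rownames(phenotypes) <- NULL

    # missing-data mask, completely at random
    dos_masked <- dos_full
    if (cfg$missing_rate > 0) {
      nmiss <- round(cfg$missing_rate * length(dos_masked))
      dos_masked[sample.int(length(dos_masked), nmiss)] <- NA_integer_
    }

    G <- geno_matrix(dos_masked, mk)
    truth <- list(p_ancestral = p_anc, stage_freq = stage_freq,
                  deme = wld$deme, deme_freq = deme_freq,
                  founder_ids = ids[meta$subgroup == "NS"][
                    seq_len(cfg$n_founders_stage2)],
                  grandparent_ids = ids[meta$subgroup == "NS"][
                    seq_len(min(extra_gp_idx, length(ns)))],
                  qtl = qtl_table, beta = beta, breeding_values = bv,
                  spatial_field = surf, field_position =
                    data.frame(accession_id = ids, row = frow, col = fcol),
                  dosages_complete = dos_full, seed = seed)
    structure(list(genotypes = G, metadata = meta, phenotypes = phenotypes,
                   truth = truth, config = cfg),
              class = "sim_panel")
  })
}

# smooth unit-variance surface on a side x side grid (sum of low-frequency
# cosine waves)
smooth_surface <- function(side) {
  g <- expand.grid(r = seq_len(side), c = seq_len(side))
  z <- numeric(nrow(g))
  for (k in 1:4) {
    fr <- stats::runif(1, 0.2, 1.2) / side
    fc <- stats::runif(1, 0.2, 1.2) / side
    z <- z + stats::rnorm(1) * cos(2 * pi * (fr * g$r + fc * g$c) +
                                     stats::runif(1, 0, 2 * pi))
  }
  z <- (z - mean(z)) / stats::sd(z)
  matrix(z, side, side)
}

#' @export
print.sim_panel <- function(x, ...) {
  tab <- table(x$metadata$subgroup)
  cat("simulated panel: ", nrow(x$genotypes$dosages), " accessions (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
      ncol(x$genotypes$dosages), " markers, seed ", x$truth$seed, "\n",
      sep = "")
  invisible(x)
}

#' Write small frozen test panels
#'
#' Emits a deterministic miniature panel (default 40 accessions x 200
#' markers) as plain-text artifacts: `sim.vcf`, `panel_metadata.tsv`,
#' `phenotypes.tsv` and `truth.json`. Byte-identical across runs with the
#' same seed.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param config optional [scenario_config()] override.
#' @return invisible character vector of the written paths.
#' @export
make_fixtures <- function(dir, seed = 20260924, config = NULL) {
  cfg <- config %||% scenario_config(
    n_wld = 12L, n_ns = 12L, n_clt1 = 8L, n_clt2 = 8L,
    n_markers = 200L, n_founders_stage2 = 5L, n_grandparents_stage3 = 6L,
    n_polygenes = 60L, years = 2L, missing_rate = 0.05)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_panel(cfg, seed = seed)
  paths <- c(vcf = file.path(dir, "sim.vcf"),
             meta = file.path(dir, "panel_metadata.tsv"),
             pheno = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$genotypes, paths["vcf"])
  write_tsv(sim$metadata, paths["meta"])
  ph <- sim$phenotypes
  ph$value <- round(ph$value, 6)
  write_tsv(ph, paths["pheno"])
  truth <- list(p_ancestral = round(sim$truth$p_ancestral, 8),
                stage_freq = round(sim$truth$stage_freq, 8),
                founder_ids = sim$truth$founder_ids,
                qtl = sim$truth$qtl, seed = seed)
  writeLines(jsonlite::toJSON(truth, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), paths["truth"])
  invisible(paths)
}
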