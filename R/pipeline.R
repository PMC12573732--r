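#' Pipeline configuration
#'
#' One configuration object driving the whole analysis chain
#' (simulate -> QC -> map -> Marey -> scans -> regional heritability ->
#' power -> enrichment). Defaults mirror the study conditions: 192 F2
#' clones, genotyping error 0.001, distortion tolerance 0.001, 1000 scan
#' permutations, 20/10 cM regional windows with 1000 permutations, 10,000
#' enrichment resamples, power at n = 192 / 0.8 cM / alpha = 0.01. The
#' \code{reduced} preset scales the expensive stages down (96 F2s, fewer
#' markers, 50-permutation nulls) for smoke runs; statistical conventions
#' are unchanged.
#'
#' @param seed Master seed; every stage derives a child seed from it by
#'   stable name hashing, so toggling one stage never shifts another's
#'   randomness.
#' @param reduced Use the reduced-scale preset.
#' @param ... Overrides for any config field.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(seed = 1L, reduced = FALSE, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_f2 = 192L,
    n_markers = c(170L, 112L, 62L, 140L),
    error_rate = 0.001, missing_rate = 0.05,
    prop_uninformative = 0.05, prop_f0_het = 0.02, prop_distorted = 0.02,
    rearrangements = list(A1 = c(3L, -1L, -2L)),
    suppression = list(A2 = c(5, 20)),
    distortion_p = 0.001,
    lod_limit = 31, size_limit = 20, join_lod = 3, order_runs = 10,
    error_lod_threshold = 5,
    scan_step = 1, scan_perms = 1000,
    rhm_width = 20, rhm_slide = 10, rhm_perms = 1000, rhm_top = 2,
    enrich_resamples = 10000, gene_clustering = 0.5,
    power_n = 192L, power_spacing = 0.8, power_alpha = 0.01,
    stages = c(simulate = TRUE, qc = TRUE, map = TRUE, marey = TRUE,
               scan = TRUE, rhm = TRUE, power = TRUE, enrich = TRUE),
    geno_file = NULL, pheno_file = NULL, map_file = NULL)
  if (reduced) {
    cfg$n_f2 <- 96L
    cfg$n_markers <- c(40L, 24L, 24L, 32L)
    cfg$lod_limit <- 6
    cfg$size_limit <- 8
    cfg$order_runs <- 4
    cfg$scan_step <- 5
    cfg$scan_perms <- 100
    cfg$rhm_width <- 50
    cfg$rhm_slide <- 25
    cfg$rhm_perms <- 50
    cfg$rhm_top <- 1
    cfg$enrich_resamples <- 1000
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "RunConfig")
}

pipeLog <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [pipeline] ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing every
#' intermediate in the documented plain-text formats under \code{outdir},
#' and returns (and writes) a run report aggregating QC counts, map
#' summaries, rearrangement calls, scan peaks, regional-heritability
#' results, the power table and enrichment tests. A fixed master seed gives
#' a byte-identical report.
#'
#' @param config A \code{\link{runConfig}}.
#' @param outdir Output directory (created if needed).
#' @return The report list, invisibly; written to \code{report.json}.
#' @export
runPipeline <- function(config = runConfig(), outdir = tempfile("aphidqtl_")) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(outdir, "run.log"), "w")
  on.exit(close(logcon), add = TRUE)
  report <- list(config = config[setdiff(names(config), "stages")],
                 stages_run = names(which(config$stages)))
  st <- config$stages

  ## -- simulate ---------------------------------------------------------
  cross <- NULL
  if (st[["simulate"]]) {
    pipeLog(logcon, "simulate: n_f2=", config$n_f2,
            " seed=", childSeed(config$seed, "simulate"))
    cc <- crossConfig(
      n_f2 = config$n_f2, n_markers = config$n_markers,
      error_rate = config$error_rate, missing_rate = config$missing_rate,
      prop_uninformative = config$prop_uninformative,
      prop_f0_het = config$prop_f0_het,
      prop_distorted = config$prop_distorted,
      rearrangements = config$rearrangements,
      suppression = config$suppression,
      seed = childSeed(config$seed, "simulate"))
    cross <- simulateCross(cc)
    writeCross(cross, file.path(outdir, "genotypes.csv"),
               file.path(outdir, "phenotypes.csv"),
               file.path(outdir, "map_true.tsv"))
    report$simulate <- list(n_f2 = nrow(cross@geno),
                            n_markers = ncol(cross@geno),
                            marker_status = as.list(table(cross@truth$marker_flags$status)))
  } else {
    pipeLog(logcon, "simulate disabled: reading user files")
    cross <- readCross(config$geno_file, config$pheno_file)
    if (!is.null(config$map_file)) {
      m <- readMapTSV(config$map_file)
      cross@map <- m[match(cross@map$marker, m$marker), ]
    }
  }

  ## -- qc ---------------------------------------------------------------
  retained <- colnames(cross@geno)
  if (st[["qc"]] && length(cross@founders)) {
    fm <- filterMarkers(cross, p_threshold = config$distortion_p)
    retained <- fm$retained
    utils::write.table(fm$report, file.path(outdir, "qc_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(as.list(fm$counts), file.path(outdir, "qc_report.json"),
                         auto_unbox = TRUE)
    report$qc <- as.list(fm$counts)
    pipeLog(logcon, "qc: retained ", length(retained), "/", ncol(cross@geno))
  }

  sub <- cross@geno[, retained, drop = FALSE]
  submap <- cross@map[match(retained, cross@map$marker), ]

  ## -- map --------------------------------------------------------------
  est_map <- NULL
  if (st[["map"]]) {
    pipeLog(logcon, "map: pairwise rf on ", length(retained), " markers")
    rf <- estimateRFMatrix(sub, error_rate = config$error_rate)
    grp <- groupMarkers(rf$lod, config$lod_limit, config$size_limit,
                        config$join_lod)
    orders <- list()
    for (g in names(grp$groups)) {
      mk <- grp$groups[[g]]
      if (length(mk) < 3) next
      bp <- stats::setNames(submap$bp, submap$marker)[mk]
      om <- orderMarkers(rf$r[mk, mk], bp = bp, n_runs = config$order_runs,
                         seed = childSeed(config$seed, paste0("order_", g)))
      orders[[g]] <- om$order
    }
    bp_all <- stats::setNames(submap$bp, submap$marker)
    est_map <- buildGeneticMap(orders, rf$r, bp = bp_all)
    if (length(orders)) {
      ## keep the true chromosome name of the majority of each group's markers
      lab <- vapply(names(orders), function(g) {
        names(sort(table(submap$chr[submap$marker %in% orders[[g]]]),
                   decreasing = TRUE))[1]
      }, "")
      est_map$chr_assembly <- lab[est_map$chr]
    }
    writeMapTSV(est_map, file.path(outdir, "map_estimated.tsv"))
    el <- errorLodFlag(cross, error_prob = max(config$error_rate, 1e-4),
                       threshold = config$error_lod_threshold)
    report$map <- list(
      n_groups = length(orders),
      group_sizes = vapply(orders, length, 1L),
      map_lengths = if (length(orders))
        vapply(split(est_map$cM, est_map$chr), max, 0) else numeric(),
      error_lod_flagged = length(el$flagged))
    pipeLog(logcon, "map: ", length(orders), " groups; lengths ",
            paste(round(report$map$map_lengths, 1), collapse = "/"))
  }

  ## -- marey ------------------------------------------------------------
  if (st[["marey"]]) {
    marey_res <- list()
    blocks_tab <- NULL
    supp_tab <- NULL
    for (chr in unique(cross@map$chr)) {
      mm <- cross@map[cross@map$chr == chr, ]
      if (nrow(mm) < 12) next
      ## jump threshold scaled to marker density so sparse gaps within a
      ## collinear run are not mistaken for breakpoints
      jump_mb <- max(2, 8 * stats::median(diff(sort(mm$bp))) / 1e6)
      seg <- segmentMarey(mm, jump_threshold_mb = jump_mb)
      arr <- seg$arrangement
      inv <- if (length(arr) <= 10) minInversionEvents(arr) else NA_integer_
      marey_res[[chr]] <- list(arrangement = arr, min_inversions = inv)
      bt <- seg$blocks; bt$chr <- chr
      blocks_tab <- rbind(blocks_tab, bt)
      sp <- detectSuppression(mm)
      if (nrow(sp)) { sp$chr <- chr; supp_tab <- rbind(supp_tab, sp) }
    }
    utils::write.table(blocks_tab, file.path(outdir, "marey_blocks.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeSuppressedBED(if (is.null(supp_tab))
      data.frame(chr = character(), bp_start = numeric(), bp_end = numeric())
      else supp_tab, file.path(outdir, "suppressed.bed"))
    report$marey <- lapply(marey_res, function(x)
      list(arrangement = x$arrangement, min_inversions = x$min_inversions))
    report$marey_suppressed <- if (is.null(supp_tab)) 0L else nrow(supp_tab)
    pipeLog(logcon, "marey: ", length(marey_res), " chromosomes segmented")
  }

  ## -- scan -------------------------------------------------------------
  regions_found <- NULL
  if (st[["scan"]]) {
    gp <- calcGenoprob(cross, step = config$scan_step,
                       error_prob = max(config$error_rate, 1e-4))
    traits <- intersect(c("acceptance_pea", "acceptance_alfalfa",
                          "survival_pea", "survival_alfalfa"),
                        names(cross@pheno))
    report$scan <- list()
    scan_rows <- NULL
    for (tr in traits) {
      y <- cross@pheno[[tr]]
      model <- if (grepl("acceptance", tr)) "nonparametric" else "twopart"
      sc <- if (model == "nonparametric") scanNonparametric(gp, y, trait = tr)
            else scanTwopart(gp, y, trait = tr)
      thr <- scanPermutationThreshold(gp, y, model, B = config$scan_perms,
                                      seed = childSeed(config$seed, paste0("scan_", tr)))
      sc <- scanSignificantPeaks(sc, as.numeric(thr))
      scan_rows <- rbind(scan_rows, cbind(trait = tr, sc@lod[c("chr", "pos", "lod")]))
      report$scan[[tr]] <- list(
        model = model, threshold = as.numeric(thr),
        max_lod = max(sc@lod$lod),
        peaks = if (nrow(sc@peaks)) sc@peaks else NULL)
      if (nrow(sc@peaks)) {
        for (k in seq_len(nrow(sc@peaks))) {
          pk <- sc@peaks[k, ]
          mm <- cross@map[cross@map$chr == pk$chr, ]
          sel <- mm$cM >= pk$lo & mm$cM <= pk$hi
          if (any(sel))
            regions_found <- rbind(regions_found, data.frame(
              region = paste0("qtl_", tr, "_", pk$chr), chr = pk$chr,
              start = min(mm$bp[sel]) - 1, end = max(mm$bp[sel]),
              stringsAsFactors = FALSE))
        }
      }
      pipeLog(logcon, "scan ", tr, ": max LOD ",
              round(max(sc@lod$lod), 2), " thr ", round(as.numeric(thr), 2))
    }
    utils::write.table(scan_rows, file.path(outdir, "scan.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  ## -- rhm --------------------------------------------------------------
  if (st[["rhm"]]) {
    windows <- defineWindows(cross@map, config$rhm_width, config$rhm_slide)
    report$rhm <- list(n_windows = nrow(windows))
    rhm_traits <- intersect(c("acceptance_pea", "acceptance_alfalfa",
                              "count_pea", "count_alfalfa"),
                            names(cross@pheno))
    for (tr in rhm_traits) {
      y <- cross@pheno[[tr]]
      fam <- if (grepl("count", tr)) "binomial" else "gaussian"
      rs <- regionalScan(y, cross@geno, cross@map, windows, family = fam)
      top <- order(rs$windows$Vr, decreasing = TRUE)[seq_len(min(config$rhm_top,
        sum(!is.na(rs$windows$Vr))))]
      sig <- NULL
      for (k in top) {
        w <- rs$windows[k, ]
        inw <- cross@map$chr == w$chr & cross@map$cM >= w$start &
          cross@map$cM < w$end
        pt <- regionalPermutationTest(
          y, computeGRM(cross@geno, cross@map$marker[inw]),
          computeGRM(cross@geno, cross@map$marker[!inw]),
          B = config$rhm_perms,
          seed = childSeed(config$seed, paste0("rhm_", tr, "_", k)),
          family = fam, force = TRUE)
        rs$windows$cutoff <- NA_real_
        rs$windows$cutoff[k] <- pt$cutoff
        if (pt$exceeds) {
          sig <- rbind(sig, w)
          mm <- cross@map[inw, ]
          if (nrow(mm))
            regions_found <- rbind(regions_found, data.frame(
              region = paste0("rhb_", tr, "_", w$chr, "_", w$start), chr = w$chr,
              start = min(mm$bp) - 1, end = max(mm$bp), stringsAsFactors = FALSE))
        }
      }
      utils::write.table(rs$windows, file.path(outdir, paste0("rhm_", tr, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      report$rhm[[tr]] <- list(
        h2_overall = rs$h2_overall,
        top_window = rs$windows[which.max(rs$windows$Vr),
                                c("chr", "start", "end", "Vr")],
        n_exceeding = if (is.null(sig)) 0L else nrow(sig))
      pipeLog(logcon, "rhm ", tr, ": overall h2 ", round(rs$h2_overall, 3))
    }
    jsonlite::write_json(lapply(report$rhm[rhm_traits], function(x)
      list(h2_overall = x$h2_overall)),
      file.path(outdir, "rhm_h2.json"), auto_unbox = TRUE, digits = NA)
  }

  ## -- power ------------------------------------------------------------
  if (st[["power"]]) {
    pt <- powerTable(n = config$power_n, spacing = config$power_spacing,
                     alpha = config$power_alpha)
    utils::write.table(pt, file.path(outdir, "power.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    report$power <- pt
    pipeLog(logcon, "power: ", nrow(pt), " scenarios")
  }

  ## -- enrich -----------------------------------------------------------
  if (st[["enrich"]]) {
    genes <- simulateGenePositions(
      crossConfig(seed = 1L), clustering = config$gene_clustering,
      seed = childSeed(config$seed, "genes"))
    if (is.null(regions_found)) {
      report$enrich <- list(note = "no significant regions; enrichment skipped")
    } else {
      gir <- genesInRegions(genes, regions_found, map = cross@map)
      subset <- genes$gene[genes$category == "OR"]
      perm <- regionEnrichmentPermutation(genes, subset, regions_found,
                                          B = config$enrich_resamples,
                                          seed = childSeed(config$seed, "enrich"))
      n_in <- length(gir$union)
      n_or_in <- sum(genes$category[genes$gene %in% gir$union] == "OR")
      fe <- if (n_in > 0)
        fisherEnrichment(orEnrichmentTable(
          n_or = sum(genes$category == "OR"), n_total = nrow(genes),
          n_in = n_in, n_or_in = n_or_in))
      else list(p_two_sided = NA_real_)
      report$enrich <- list(genes_in_regions = n_in,
                            or_in_regions = n_or_in,
                            permutation = perm,
                            fisher_p = fe$p_two_sided)
      pipeLog(logcon, "enrich: ", n_in, " genes in regions; perm p ",
              signif(perm$p, 3))
    }
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  pipeLog(logcon, "done: report at ", file.path(outdir, "report.json"))
  invisible(report)
}
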