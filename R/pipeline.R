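#' Default pipeline configuration values
#'
#' @return Named list of defaults: `evalue_max` 0.001, `core_length` 60,
#'   `gap_mask` 0.5, `gap_open` 11, `gap_ext` 1, `lambda` 0.267, `K` 0.041,
#'   `schemes` PC and BS.
#' @export
pipeline_defaults <- function() {
  list(evalue_max = 0.001, core_length = 60L, gap_mask = 0.5,
       gap_open = 11L, gap_ext = 1L, lambda = 0.267, K = 0.041,
       schemes = c("PC", "BS"))
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- pipeline_defaults()
  cfg[names(config)] <- config
  need <- c("proteome_dir", "level_table", "protein_sets", "reference", "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("pipeline config is missing: ", paste(miss, collapse = ", "))
  for (p in c("proteome_dir", "level_table", "protein_sets")) {
    if (!file.exists(cfg[[p]])) stop("missing input (", p, "): ", cfg[[p]])
  }
  cfg
}

rebuild_family <- function(rid, level_name, fam_tab, proteomes, ref_species, level) {
  rows <- fam_tab[fam_tab$ref_id == rid, , drop = FALSE]
  ref_tab <- proteomes[[ref_species]]
  orth <- if (nrow(rows)) {
    data.frame(id = rows$ortholog_id, species = rows$species,
               seq = vapply(seq_len(nrow(rows)), function(i) {
                 p <- proteomes[[rows$species[i]]]
                 p$seq[p$id == rows$ortholog_id[i]]
               }, character(1)),
               pct_identity = rows$pct_identity, bitscore = rows$bitscore,
               self_bitscore = rows$self_bitscore, stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(), species = character(), seq = character(),
               pct_identity = numeric(), bitscore = numeric(),
               self_bitscore = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(ref = list(id = rid, species = ref_species,
                            seq = ref_tab$seq[ref_tab$id == rid]),
                 level_species = level, orthologs = orth,
                 flagged = nrow(orth) == 0L),
            class = "ortholog_family")
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the whole conservation analysis pipeline
#'
#' Orchestrates the stages: load proteomes and tables, detect orthologs
#' (BDBH) and build families per taxonomic level, align each family,
#' score per-column conservation and domain means, score prion-like
#' composition, compute the EWPS under both weightings, and write the
#' comparison-layer tables. All outputs are TSVs under `out_dir`; a
#' `manifest.json` records package version and parameters. Re-running with
#' the same configuration skips stages whose outputs exist (byte-identical
#' results) unless `force = TRUE`.
#'
#' @param config Path to a YAML file or a list with at least
#'   `proteome_dir` (directory of `<species>.fasta`), `level_table`,
#'   `protein_sets`, `reference` (species name) and `out_dir`; optional
#'   keys override [pipeline_defaults()], and `alignment_dir` supplies
#'   precomputed per-family alignments named `<ref_id>.<level>.afa`.
#' @param force Recompute stages whose outputs already exist.
#' @return Invisibly, a list with the per-level summary tables and the
#'   paths of everything written.
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- align_params(cfg$gap_open, cfg$gap_ext, cfg$lambda, cfg$K)
  tables <- default_frequency_tables()

  fasta <- list.files(cfg$proteome_dir, pattern = "\\.(fa|fasta|faa)$",
                      full.names = TRUE)
  if (length(fasta) == 0L) stop("no FASTA files in ", cfg$proteome_dir)
  proteomes <- lapply(fasta, read_fasta)
  names(proteomes) <- vapply(fasta, function(p) sub("\\.[A-Za-z0-9]+$", "", basename(p)),
                             character(1))
  if (!cfg$reference %in% names(proteomes)) {
    stop("reference species '", cfg$reference, "' has no proteome")
  }
  levels <- load_level_table(cfg$level_table, proteomes = names(proteomes))
  psets <- load_protein_sets(cfg$protein_sets)
  ref_tab <- proteomes[[cfg$reference]]
  ref_ids <- intersect(psets$accession, ref_tab$id)
  if (length(ref_ids) == 0L) stop("no protein-set accession found in the reference proteome")

  aln_dir <- file.path(cfg$out_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  outputs <- character(0)
  summaries <- list()

  for (lv in names(levels)) {
    fam_path <- file.path(cfg$out_dir, sprintf("families_%s.tsv", lv))
    if (force || !file.exists(fam_path)) {
      fams <- build_families(ref_ids, proteomes, levels[[lv]], cfg$reference,
                             cfg$evalue_max, params)
      write_tsv(families_table(fams), fam_path)
    } else {
      fam_tab <- read.delim(fam_path, stringsAsFactors = FALSE)
      fams <- lapply(ref_ids, rebuild_family, lv, fam_tab, proteomes,
                     cfg$reference, levels[[lv]])
    }
    names(fams) <- ref_ids
    outputs <- c(outputs, fam_path)

    per_protein <- list()
    for (rid in ref_ids) {
      fam <- fams[[rid]]
      meta <- psets[psets$accession == rid, ]
      # prion scores for every family member; SCPS = reference's own score
      scores <- score_family(fam, tables, cfg$core_length)
      scps <- scores$prd_score[1L]
      ref_pred <- score_sequence(fam$ref, tables, cfg$core_length)

      dm <- wm <- list(mean = NA_real_, sd = NA_real_)
      if (!fam$flagged) {
        apath <- file.path(
          if (!is.null(cfg$alignment_dir)) cfg$alignment_dir else aln_dir,
          sprintf("%s.%s.afa", rid, lv))
        if (file.exists(apath) && !(force && is.null(cfg$alignment_dir))) {
          block <- read_aligned_fasta(apath)
        } else {
          block <- progressive_align(fam, params)
          write_aligned_fasta(block, file.path(aln_dir, sprintf("%s.%s.afa", rid, lv)))
        }
        prof <- column_conservation(block, cfg$gap_mask)
        # experimental boundaries if given, predicted otherwise
        interval <- if (!is.na(meta$domain_start)) {
          c(meta$domain_start, meta$domain_end)
        } else ref_pred$domain_interval
        if (!is.null(interval) && !any(is.na(interval))) {
          cols <- map_domain_to_columns(block, rid, interval)
          dm <- domain_mean_conservation(prof, cols)
        }
        wm <- domain_mean_conservation(prof)
      }

      orth_scores <- scores$prd_score[-1L]
      e_pc <- compute_ewps(fam, orth_scores, "PC")
      e_bs <- compute_ewps(fam, orth_scores, "BS")
      per_protein[[rid]] <- data.frame(
        ref_id = rid, category = meta$category, level = lv,
        n_orthologs = nrow(fam$orthologs),
        domain_mean_cons = dm$mean, domain_sd_cons = dm$sd,
        whole_mean_cons = wm$mean, whole_sd_cons = wm$sd,
        scps = scps, llr = ref_pred$llr,
        ewps_pc = e_pc$ewps, ewps_bs = e_bs$ewps,
        flagged = fam$flagged, stringsAsFactors = FALSE)
    }
    summary_lv <- do.call(rbind, per_protein)
    rownames(summary_lv) <- NULL
    sp_path <- file.path(cfg$out_dir, sprintf("summary_%s.tsv", lv))
    if (force || !file.exists(sp_path)) write_tsv(summary_lv, sp_path)
    outputs <- c(outputs, sp_path)
    summaries[[lv]] <- summary_lv
  }

  stats_out <- pipeline_stats(summaries, psets)
  for (nm in names(stats_out)) {
    p <- file.path(cfg$out_dir, paste0(nm, ".tsv"))
    if (force || !file.exists(p)) write_tsv(stats_out[[nm]], p)
    outputs <- c(outputs, p)
  }

  manifest <- file.path(cfg$out_dir, "manifest.json")
  if (force || !file.exists(manifest)) {
    keep <- cfg[setdiff(names(cfg), "schemes")]
    jsonlite::write_json(
      list(package = "prionevo",
           version = as.character(utils::packageVersion("prionevo")),
           parameters = keep,
           levels = lapply(levels, identity),
           n_reference_proteins = length(ref_ids)),
      manifest, auto_unbox = TRUE, pretty = TRUE)
  }
  outputs <- c(outputs, manifest)
  invisible(list(summaries = summaries, stats = stats_out,
                 outputs = outputs, config = cfg))
}

# The comparison layer over per-level summaries: set-vs-set tests on
# conservation means, EWPS correlations, thirds consistency, top-10s.
pipeline_stats <- function(summaries, psets) {
  out <- list()
  sets <- c("KP", "PFP_minus_KP", "PLP")
  # pairwise Welch tests on domain and whole-sequence mean conservation
  tests <- list()
  for (lv in names(summaries)) {
    s <- summaries[[lv]]
    for (i in 1:2) for (j in (i + 1):3) {
      ga <- s[s$ref_id %in% set_members(psets, sets[i]), ]
      gb <- s[s$ref_id %in% set_members(psets, sets[j]), ]
      for (what in c("domain_mean_cons", "whole_mean_cons")) {
        va <- ga[[what]][!is.na(ga[[what]])]
        vb <- gb[[what]][!is.na(gb[[what]])]
        if (length(va) < 2L || length(vb) < 2L) next
        wt <- welch_t(va, vb)
        tests[[length(tests) + 1L]] <- data.frame(
          level = lv, set_a = sets[i], set_b = sets[j], measure = what,
          mean_a = mean(va), mean_b = mean(vb),
          t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
      }
      # EWPS set comparisons (Mann-Whitney)
      ea <- ga$ewps_pc[!is.na(ga$ewps_pc)]; eb <- gb$ewps_pc[!is.na(gb$ewps_pc)]
      if (length(ea) >= 1L && length(eb) >= 1L) {
        mw <- mann_whitney(ea, eb)
        tests[[length(tests) + 1L]] <- data.frame(
          level = lv, set_a = sets[i], set_b = sets[j], measure = "ewps_pc",
          mean_a = mean(ea), mean_b = mean(eb),
          t = mw$U, df = NA_real_, p = mw$p, stringsAsFactors = FALSE)
      }
    }
  }
  out$set_tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(level = character(), set_a = character(), set_b = character(),
               measure = character(), mean_a = numeric(), mean_b = numeric(),
               t = numeric(), df = numeric(), p = numeric())

  # correlations of EWPS with SCPS and with sequence conservation
  cors <- list()
  for (lv in names(summaries)) {
    s <- summaries[[lv]]
    for (setn in c("PFP", "PLP")) {
      g <- s[s$ref_id %in% set_members(psets, setn), ]
      for (scheme in c("ewps_pc", "ewps_bs")) {
        for (against in c("scps", "domain_mean_cons")) {
          keep <- !is.na(g[[scheme]]) & !is.na(g[[against]])
          if (sum(keep) < 3L) next
          pr <- pearson_r(g[[scheme]][keep], g[[against]][keep])
          cors[[length(cors) + 1L]] <- data.frame(
            level = lv, set = setn, scheme = scheme, against = against,
            r = pr$r, p = pr$p, n = pr$n, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out$correlations <- if (length(cors)) do.call(rbind, cors) else
    data.frame(level = character(), set = character(), scheme = character(),
               against = character(), r = numeric(), p = numeric(), n = numeric())

  # thirds consistency of domain mean conservation across levels (PFP set)
  pfp <- set_members(psets, "PFP")
  by_level <- lapply(summaries, function(s) {
    v <- s$domain_mean_cons[s$ref_id %in% pfp]
    names(v) <- s$ref_id[s$ref_id %in% pfp]
    v[!is.na(v)]
  })
  common <- Reduce(intersect, lapply(by_level, names))
  if (length(common) >= 3L) {
    th <- thirds_consistency(lapply(by_level, function(v) v[common]))
    out$thirds <- data.frame(ref_id = rownames(th$thirds), th$thirds,
                             stable = rownames(th$thirds) %in% th$stable_ids,
                             row.names = NULL, stringsAsFactors = FALSE)
    out$thirds_summary <- data.frame(
      n = length(common), fraction_stable = th$fraction_stable,
      n_traverse_all = length(th$traverse_all_ids))
  }

  # top-10 rankings at the broadest level
  broad <- names(summaries)[which.max(vapply(summaries, nrow, integer(1)))]
  s <- summaries[[broad]]
  out$top10_ewps <- top_k_table(s, "ewps_pc", 10L)
  out$top10_conservation <- top_k_table(s, "domain_mean_cons", 10L)
  out
}
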