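#' Configuration for the ortholog-family simulator
#'
#' The simulator emulates the evolutionary scenario the analysis assumes:
#' families of orthologous proteins descended from a common ancestor that
#' carries one N/Q-rich segment embedded in ordinary-composition flanks,
#' evolving across three nested clades (genus within whole-genome
#' duplication group within class). Each species diverges from the ancestor
#' by a level-specific depth (expected substitutions per flank site);
#' domain sites substitute at `domain_rate_mult` times the flank rate.
#' Substitutions resample the site from a stationary composition (flank:
#' proteome-like background; domain: N/Q-enriched), so composition is
#' preserved in expectation. Indels arrive per site at `indel_rate` per
#' unit depth with geometric lengths.
#'
#' The reference species (`sp01`) keeps the ancestral sequence; the other
#' species of the genus / WGD group / class diverge by `depth_genus` /
#' `depth_wgd` / `depth_class`.
#'
#' @param n_genus,n_wgd,n_class Cumulative species counts at the three
#'   nested levels (including the reference; `n_genus <= n_wgd <=
#'   n_class`). Defaults 2 / 4 / 8.
#' @param depth_genus,depth_wgd,depth_class Expected flank substitutions
#'   per site from the ancestor for species whose innermost level is the
#'   genus / WGD group / class.
#' @param domain_rate_mult Substitution-rate multiplier for domain sites.
#' @param indel_rate Indel events per site per unit depth.
#' @param indel_mean_len Mean indel length (geometric).
#' @param flank_length Length of each flank in the ancestor.
#' @param domain_length Length of the planted N/Q-rich segment.
#' @param domain_nq_frac Combined N+Q fraction of the domain composition
#'   (split 60:40 between N and Q; the remainder follows the background).
#' @param seed Integer seed fixing all randomness, or NULL to use the
#'   current RNG state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genus = 2L, n_wgd = 4L, n_class = 8L,
                       depth_genus = 0.1, depth_wgd = 0.3, depth_class = 0.6,
                       domain_rate_mult = 1,
                       indel_rate = 0.02, indel_mean_len = 2,
                       flank_length = 40L, domain_length = 60L,
                       domain_nq_frac = 0.8, seed = NULL) {
  stopifnot(n_genus >= 1L, n_genus <= n_wgd, n_wgd <= n_class,
            depth_genus >= 0, depth_wgd >= 0, depth_class >= 0,
            domain_rate_mult >= 0, indel_rate >= 0, indel_mean_len >= 1,
            flank_length >= 0, domain_length >= 1L,
            domain_nq_frac >= 0, domain_nq_frac <= 1)
  species <- sprintf("sp%02d", seq_len(n_class))
  depth <- c(0, rep(depth_genus, n_genus - 1L),
             rep(depth_wgd, n_wgd - n_genus),
             rep(depth_class, n_class - n_wgd))
  names(depth) <- species
  structure(list(
    species = species,
    reference = species[1L],
    levels = list(genus = species[seq_len(n_genus)],
                  wgd = species[seq_len(n_wgd)],
                  class = species),
    depth = depth,
    domain_rate_mult = domain_rate_mult,
    indel_rate = indel_rate, indel_mean_len = indel_mean_len,
    flank_length = as.integer(flank_length),
    domain_length = as.integer(domain_length),
    domain_nq_frac = domain_nq_frac,
    seed = seed
  ), class = "sim_config")
}

# Stationary compositions. Flank sites follow the shipped proteome-like
# background; domain sites put domain_nq_frac on N/Q (60:40) and spread the
# rest over the remaining residues in background proportions.
sim_compositions <- function(config) {
  bg <- default_frequency_tables()$background
  dom <- bg
  dom[c("N", "Q")] <- 0
  dom <- dom / sum(dom) * (1 - config$domain_nq_frac)
  dom["N"] <- 0.6 * config$domain_nq_frac
  dom["Q"] <- 0.4 * config$domain_nq_frac
  list(flank = bg / sum(bg), domain = dom / sum(dom))
}

sample_aa <- function(n, comp) {
  sample(names(comp), n, replace = TRUE, prob = comp)
}

# Evolve a labelled ancestor (residues + flank/domain site labels) along a
# branch of the given flank depth. Substitutions: Poisson events per site;
# any event resamples from the site label's stationary composition. Indels:
# Poisson count over sites, geometric lengths; insertions copy the label at
# the insertion point.
evolve_branch <- function(residues, labels, depth, config, comps) {
  if (depth > 0) {
    rate <- ifelse(labels == "domain", config$domain_rate_mult, 1) * depth
    hit <- rpois(length(residues), rate) > 0L
    if (any(hit)) {
      dom_hit <- hit & labels == "domain"
      fl_hit <- hit & labels != "domain"
      residues[dom_hit] <- sample_aa(sum(dom_hit), comps$domain)
      residues[fl_hit] <- sample_aa(sum(fl_hit), comps$flank)
    }
    n_indel <- rpois(1L, config$indel_rate * depth * length(residues))
    for (k in seq_len(n_indel)) {
      len <- rgeom(1L, 1 / config$indel_mean_len) + 1L
      pos <- sample.int(length(residues), 1L)
      if (runif(1L) < 0.5) {            # deletion
        del <- pos:min(pos + len - 1L, length(residues))
        if (length(del) >= length(residues)) next  # never delete everything
        residues <- residues[-del]; labels <- labels[-del]
      } else {                          # insertion after pos
        lab <- labels[pos]
        comp <- if (lab == "domain") comps$domain else comps$flank
        ins <- sample_aa(len, comp)
        residues <- append(residues, ins, after = pos)
        labels <- append(labels, rep(lab, len), after = pos)
      }
    }
  }
  list(residues = residues, labels = labels)
}

sim_tree_newick <- function(config) {
  d <- config$depth
  lv <- config$levels
  h_g <- max(config$depth[setdiff(lv$genus, config$reference)], 0.01)
  h_w <- max(config$depth[setdiff(lv$wgd, lv$genus)], h_g + 0.01)
  h_c <- max(config$depth[setdiff(lv$class, lv$wgd)], h_w + 0.01)
  genus_tips <- paste(sprintf("%s:%g", lv$genus, h_g), collapse = ",")
  genus_clade <- sprintf("(%s):%g", genus_tips, h_w - h_g)
  wgd_extra <- setdiff(lv$wgd, lv$genus)
  wgd_inner <- paste(c(genus_clade, sprintf("%s:%g", wgd_extra, h_w)),
                     collapse = ",")
  wgd_clade <- sprintf("(%s):%g", wgd_inner, h_c - h_w)
  class_extra <- setdiff(lv$class, lv$wgd)
  root <- paste(c(wgd_clade, sprintf("%s:%g", class_extra, h_c)),
                collapse = ",")
  sprintf("(%s);", root)
}

#' Simulate one ortholog family across the nested clades
#'
#' @param config A [sim_config()].
#' @param family_id Identifier stem used in sequence ids.
#' @return List: `ancestor` (sequence string), `records` (protein table:
#'   `id`, `species`, `seq`), `domain_intervals` (named list of 1-based
#'   `c(start, end)` per species, NA if the domain was lost), `tree`
#'   (`ape` phylo of the intended clade structure).
#' @export
simulate_family <- function(config, family_id = "fam01") {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$species) == 0L) stop("no species to simulate")
  if (!is.null(config$seed)) set.seed(config$seed)
  comps <- sim_compositions(config)
  anc_res <- c(sample_aa(config$flank_length, comps$flank),
               sample_aa(config$domain_length, comps$domain),
               sample_aa(config$flank_length, comps$flank))
  anc_lab <- c(rep("flank", config$flank_length),
               rep("domain", config$domain_length),
               rep("flank", config$flank_length))
  records <- vector("list", length(config$species))
  intervals <- vector("list", length(config$species))
  names(intervals) <- config$species
  for (i in seq_along(config$species)) {
    sp <- config$species[i]
    ev <- evolve_branch(anc_res, anc_lab, config$depth[[sp]], config, comps)
    dom_pos <- which(ev$labels == "domain")
    intervals[[sp]] <- if (length(dom_pos)) range(dom_pos) else c(NA_integer_, NA_integer_)
    records[[i]] <- data.frame(
      id = paste0(sp, "_", family_id), species = sp,
      seq = paste(ev$residues, collapse = ""), stringsAsFactors = FALSE)
  }
  list(ancestor = paste(anc_res, collapse = ""),
       records = do.call(rbind, records),
       domain_intervals = intervals,
       tree = ape::read.tree(text = sim_tree_newick(config)))
}

#' Simulate a proteome set with planted ortholog families and decoys
#'
#' Generates `n_families` independent families under `config`, distributes
#' one ortholog per species per family, and pads every proteome with
#' `decoy_factor * n_families` unrelated decoy proteins (independent draws
#' from the background composition, lengths matched to the family
#' sequences). Ground truth for ortholog pairs and planted domain
#' intervals is returned alongside.
#'
#' @param config A [sim_config()].
#' @param n_families Number of ortholog families.
#' @param decoy_factor Decoys per proteome as a multiple of `n_families`.
#' @return List: `proteomes` (named list of protein tables), `levels`
#'   (level -> species), `reference` (species name), `truth_pairs`
#'   (data.frame: `family`, `ref_id`, `species`, `ortholog_id`),
#'   `truth_domains` (data.frame: `id`, `species`, `family`,
#'   `domain_start`, `domain_end`), `families` (list of
#'   [simulate_family()] results).
#' @export
simulate_proteome_set <- function(config, n_families = 30L, decoy_factor = 5) {
  stopifnot(inherits(config, "sim_config"), n_families >= 1L)
  if (!is.null(config$seed)) set.seed(config$seed)
  inner <- config
  inner$seed <- NULL
  fam_ids <- sprintf("fam%03d", seq_len(n_families))
  fams <- lapply(fam_ids, function(fid) simulate_family(inner, fid))
  names(fams) <- fam_ids

  proteomes <- lapply(config$species, function(sp) {
    rows <- lapply(fams, function(f) f$records[f$records$species == sp, ])
    do.call(rbind, rows)
  })
  names(proteomes) <- config$species

  fam_lens <- unlist(lapply(fams, function(f) nchar(f$records$seq)))
  comps <- sim_compositions(config)
  n_decoys <- as.integer(round(decoy_factor * n_families))
  for (sp in config$species) {
    if (n_decoys == 0L) break
    lens <- sample(fam_lens, n_decoys, replace = TRUE)
    dec <- data.frame(
      id = sprintf("%s_dec%03d", sp, seq_len(n_decoys)), species = sp,
      seq = vapply(lens, function(L) paste(sample_aa(L, comps$flank), collapse = ""),
                   character(1)),
      stringsAsFactors = FALSE)
    proteomes[[sp]] <- rbind(proteomes[[sp]], dec)
    rownames(proteomes[[sp]]) <- NULL
  }

  ref <- config$reference
  truth_pairs <- do.call(rbind, lapply(fam_ids, function(fid) {
    rec <- fams[[fid]]$records
    others <- rec[rec$species != ref, ]
    data.frame(family = fid, ref_id = rec$id[rec$species == ref],
               species = others$species, ortholog_id = others$id,
               stringsAsFactors = FALSE)
  }))
  rownames(truth_pairs) <- NULL
  truth_domains <- do.call(rbind, lapply(fam_ids, function(fid) {
    rec <- fams[[fid]]$records
    iv <- fams[[fid]]$domain_intervals
    data.frame(id = rec$id, species = rec$species, family = fid,
               domain_start = vapply(rec$species, function(s) iv[[s]][1L], integer(1)),
               domain_end = vapply(rec$species, function(s) iv[[s]][2L], integer(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(truth_domains) <- NULL
  list(proteomes = proteomes, levels = config$levels, reference = ref,
       truth_pairs = truth_pairs, truth_domains = truth_domains,
       families = fams)
}

#' Write a simulated proteome set to disk in the pipeline's input layout
#'
#' One FASTA per species, a species/level TSV, and a protein-set TSV
#' marking every planted reference protein (category PFP, with true domain
#' boundaries).
#'
#' @param sim A [simulate_proteome_set()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$proteomes)) {
    tab <- sim$proteomes[[sp]]
    tab$desc <- tab$id
    write_fasta(tab, file.path(dir, paste0(sp, ".fasta")))
  }
  lv <- sim$levels
  species <- names(sim$proteomes)
  lt <- data.frame(species = species)
  for (nm in names(lv)) lt[[nm]] <- as.integer(species %in% lv[[nm]])
  write.table(lt, file.path(dir, "levels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ref_dom <- sim$truth_domains[sim$truth_domains$species == sim$reference, ]
  ps <- data.frame(accession = ref_dom$id, category = "PFP",
                   domain_start = ref_dom$domain_start,
                   domain_end = ref_dom$domain_end)
  write.table(ps, file.path(dir, "protein_sets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
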