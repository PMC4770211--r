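#' Default Mediator subunit panel for simulation
#'
#' Fourteen subunits spanning the Head, Middle, Tail and Kinase modules
#' with realistic lengths. Med1 is absent in plants and Med26 in fungi,
#' so the panel exercises the missing-subunit distance policies.
#'
#' @return Data frame with `subunit_id`, `length`, `absent_in`.
#' @export
default_subunit_panel <- function() {
  data.frame(
    subunit_id = c("Med6", "Med8", "Med11", "Med17", "Med19", "Med1",
                   "Med4", "Med7", "Med9", "Med21", "Med31", "Med15",
                   "Med16", "Med26"),
    length = c(245L, 270L, 120L, 560L, 220L, 580L,
               270L, 220L, 150L, 140L, 130L, 780L, 850L, 600L),
    absent_in = c("", "", "", "", "", "plantae",
                  "", "", "", "", "", "", "", "fungi"),
    stringsAsFactors = FALSE)
}

## Per-group, per-subunit mean average disorder. The three kingdom rows
## are the published per-kingdom means for these subunits; the basal row
## is the shared low-disorder signature of the early-diverging organisms
## that co-cluster across kingdoms.
default_group_signatures <- function() {
  sub <- default_subunit_panel()$subunit_id
  m <- rbind(
    metazoa_main = c(0.38, 0.50, 0.43, 0.31, 0.67, 0.57,
                     0.51, 0.40, 0.50, 0.39, 0.21, 0.59, 0.17, 0.63),
    plantae_main = c(0.39, 0.58, 0.29, 0.30, 0.67, NA,
                     0.56, 0.37, 0.56, 0.53, 0.33, 0.61, 0.34, 0.55),
    fungi_main   = c(0.41, 0.45, 0.44, 0.33, 0.61, 0.32,
                     0.52, 0.43, 0.51, 0.43, 0.27, 0.66, 0.24, NA),
    basal        = c(0.22, 0.25, 0.20, 0.18, 0.30, 0.25,
                     0.28, 0.22, 0.25, 0.22, 0.15, 0.30, 0.12, 0.28))
  colnames(m) <- sub
  m
}

#' Simulation configuration
#'
#' Defines the synthetic study: four organism groups (three kingdom
#' groups plus a cross-kingdom basal low-disorder group, 146 organisms in
#' total by default: 97 metazoans, 24 plants, 25 fungi), a subunit panel
#' with kingdom-specific mean disorder signatures, bounded Beta score laws
#' for disordered and ordered residues, and PTM placement parameters.
#'
#' @param groups List of group definitions, each a list with `name`,
#'   `composition` (named integer vector: organisms per kingdom), `means`
#'   (named numeric vector over the subunit panel; `NA` = subunit absent
#'   in that kingdom regardless), and `sd` (between-organism standard
#'   deviation of the subunit-mean offsets).
#' @param subunits Data frame as [default_subunit_panel()].
#' @param mu_disordered,mu_ordered Means of the Beta score laws inside and
#'   outside planted IDR blocks.
#' @param concentration Beta concentration (`alpha + beta`); larger is
#'   less noisy per residue.
#' @param ptm_rate Expected PTM sites per 100 residues.
#' @param ptm_idr_odds Odds multiplier for site placement inside IDRs
#'   (>= 1).
#' @param seed Master seed; every simulation output is a pure function of
#'   (config, seed).
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(groups = NULL,
                              subunits = default_subunit_panel(),
                              mu_disordered = 0.75, mu_ordered = 0.25,
                              concentration = 30,
                              ptm_rate = 5, ptm_idr_odds = 3,
                              seed = 1L) {
  if (is.null(groups)) {
    sig <- default_group_signatures()
    sd0 <- 0.02
    groups <- list(
      list(name = "metazoa_main", composition = c(metazoa = 89L),
           means = sig["metazoa_main", ], sd = sd0),
      list(name = "plantae_main", composition = c(plantae = 21L),
           means = sig["plantae_main", ], sd = sd0),
      list(name = "fungi_main", composition = c(fungi = 21L),
           means = sig["fungi_main", ], sd = sd0),
      list(name = "basal",
           composition = c(metazoa = 8L, plantae = 3L, fungi = 4L),
           means = sig["basal", ], sd = sd0))
  }
  cfg <- structure(
    list(groups = groups, subunits = subunits,
         mu_disordered = mu_disordered, mu_ordered = mu_ordered,
         concentration = concentration,
         ptm_rate = ptm_rate, ptm_idr_odds = ptm_idr_odds,
         seed = as.integer(seed)),
    class = "sim_config")
  bad <- validate_sim_config(cfg)
  if (length(bad) > 0L)
    stop(paste(c("invalid simulation config:", bad), collapse = "\n  "),
         call. = FALSE)
  cfg
}

validate_sim_config <- function(cfg) {
  out <- character(0)
  if (!(cfg$mu_disordered > 0 && cfg$mu_disordered < 1))
    out <- c(out, "mu_disordered must lie in (0, 1)")
  if (!(cfg$mu_ordered > 0 && cfg$mu_ordered < 1))
    out <- c(out, "mu_ordered must lie in (0, 1)")
  if (cfg$mu_disordered <= cfg$mu_ordered)
    out <- c(out, "mu_disordered must exceed mu_ordered")
  if (cfg$concentration <= 0) out <- c(out, "concentration must be > 0")
  if (cfg$ptm_rate < 0) out <- c(out, "ptm_rate must be >= 0")
  if (cfg$ptm_idr_odds < 1) out <- c(out, "ptm_idr_odds must be >= 1")
  for (g in cfg$groups) {
    if (sum(g$composition) < 1L)
      out <- c(out, sprintf("group %s must have >= 1 organism", g$name))
    mu <- g$means[!is.na(g$means)]
    if (any(mu <= 0 | mu >= 1))
      out <- c(out, sprintf("group %s means must lie in (0, 1)", g$name))
    if (g$sd < 0)
      out <- c(out, sprintf("group %s sd must be >= 0", g$name))
    if (!all(names(g$means) %in% cfg$subunits$subunit_id))
      out <- c(out, sprintf("group %s names unknown subunits", g$name))
  }
  out
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

## Planted IDR blocks covering `frac` of a length-L protein: a single
## C-terminal block, split into an N-terminal plus a C-terminal block for
## large fractions (mirroring the prevalence of terminal IDRs).
plan_idr_blocks <- function(L, frac, min_len = 30L) {
  B <- round(frac * L)
  if (B < min_len)
    return(data.frame(start = integer(0), end = integer(0)))
  if (B < 3L * min_len)
    return(data.frame(start = L - B + 1L, end = L))
  bN <- round(0.4 * B)
  bC <- B - bN
  data.frame(start = c(1L, L - bC + 1L), end = c(bN, L))
}

#' Simulate disorder profiles for the configured study
#'
#' For every organism and every subunit present in its kingdom, a target
#' subunit-average disorder is drawn (group signature mean plus a
#' per-organism, per-subunit Gaussian offset). IDR blocks are planted to
#' carry the disordered fraction implied by the target; per-residue
#' scores come from the disordered Beta law inside blocks and the ordered
#' law elsewhere, plus a small residual shift so the profile mean matches
#' the target. Identical seeds give byte-identical output.
#'
#' @param config A [simulation_config()].
#' @return List with `profiles` (list of [disorder_profile()]),
#'   `organisms` (data frame `organism_id`, `kingdom`, `group`), and
#'   `truth` (per-profile planted blocks and target means).
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    panel <- config$subunits
    k <- config$concentration
    mu_d <- config$mu_disordered; mu_o <- config$mu_ordered
    profiles <- list()
    blocks <- list()
    meta <- list()
    orgs <- list()
    for (g in config$groups) {
      idx <- 0L
      for (kng in names(g$composition)) {
        for (i in seq_len(g$composition[[kng]])) {
          idx <- idx + 1L
          org <- sprintf("%s_%03d", g$name, idx)
          orgs[[org]] <- data.frame(organism_id = org, kingdom = kng,
                                    group = g$name,
                                    stringsAsFactors = FALSE)
          for (si in seq_len(nrow(panel))) {
            sub <- panel$subunit_id[si]
            L <- panel$length[si]
            if (panel$absent_in[si] == kng) next
            m0 <- g$means[[sub]]
            if (is.na(m0)) next
            m <- min(max(m0 + stats::rnorm(1L, 0, g$sd), 0.05), 0.92)
            frac <- min(max((m - mu_o) / (mu_d - mu_o), 0), 0.85)
            blk <- plan_idr_blocks(L, frac)
            B <- if (nrow(blk)) sum(blk$end - blk$start + 1L) else 0L
            mu <- rep(mu_o, L)
            for (bi in seq_len(nrow(blk)))
              mu[blk$start[bi]:blk$end[bi]] <- mu_d
            shift <- m - (B / L * mu_d + (1 - B / L) * mu_o)
            sc <- stats::rbeta(L, mu * k, (1 - mu) * k) + shift
            sc <- pmin(pmax(sc, 0), 1)
            seq_str <- paste(sample(AA20, L, replace = TRUE),
                             collapse = "")
            key <- paste(org, sub, sep = "|")
            profiles[[key]] <- disorder_profile(org, sub, kng, seq_str, sc)
            blocks[[key]] <- blk
            meta[[key]] <- data.frame(
              organism_id = org, kingdom = kng, group = g$name,
              subunit_id = sub, target_mean = m,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    list(profiles = profiles,
         organisms = do.call(rbind, c(orgs, list(make.row.names = FALSE))),
         truth = list(blocks = blocks,
                      meta = do.call(rbind,
                                     c(meta, list(make.row.names = FALSE)))))
  })
}

#' Simulate a PTM track for one profile
#'
#' Sites are placed independently per position with inside-IDR odds
#' multiplied by `idr_odds`, scaled so the expected site count equals
#' `rate` per 100 residues. A zero rate yields an empty track.
#'
#' @param profile A [disorder_profile()].
#' @param idr_blocks Data frame of planted (or called) IDR intervals.
#' @param rate Expected sites per 100 residues.
#' @param idr_odds Odds multiplier for positions inside IDRs (>= 1).
#' @param seed Optional seed for reproducibility.
#' @return A [ptm_track()].
#' @export
simulate_ptm_track <- function(profile, idr_blocks, rate = 5,
                               idr_odds = 3, seed = NULL) {
  stopifnot(rate >= 0, idr_odds >= 1)
  L <- nchar(profile$sequence)
  with_seed(seed, {
    if (rate == 0)
      return(ptm_track(integer(0), character(0), L,
                       profile$organism_id, profile$subunit_id))
    inside <- rep(FALSE, L)
    for (i in seq_len(NROW(idr_blocks)))
      inside[idr_blocks$start[i]:idr_blocks$end[i]] <- TRUE
    n_in <- sum(inside); n_out <- L - n_in
    p0 <- (rate / 100 * L) / (n_out + idr_odds * n_in)
    p <- ifelse(inside, pmin(idr_odds * p0, 1), pmin(p0, 1))
    hit <- which(stats::runif(L) < p)
    types <- sample(PTM_TYPES, length(hit), replace = TRUE,
                    prob = c(0.30, 0.15, 0.05, 0.15, 0.15, 0.10, 0.10))
    ptm_track(hit, types, L, profile$organism_id, profile$subunit_id)
  })
}

#' Simulate homolog alignments with planted MoRFs
#'
#' Generates an ancestor sequence, derives homologs by uniform
#' substitution and residue deletion (the true alignment is retained by
#' construction: rows keep the ancestor's column frame with `-` at
#' deletions), and plants high-scoring MoRF blocks at homologous columns
#' in a configured organism subset; elsewhere MoRF scores follow a low
#' background law.
#'
#' @param n_organisms Number of homologs (>= 4; conservation is untestable
#'   below the 4-organism threshold).
#' @param width Ancestor length = alignment width (columns).
#' @param sub_rate Per-residue substitution probability.
#' @param indel_rate Per-residue deletion probability (0 = ungapped).
#' @param morf_blocks Data frame of planted column intervals (`start`,
#'   `end`); `NULL` plants two 12-column blocks at 20% and 60% of the
#'   width (one when the alignment is too narrow for two).
#' @param morf_organisms Organisms carrying the planted MoRFs (default:
#'   the first 6, or all if fewer).
#' @param mu_morf,mu_background Means of the Beta MoRF score laws.
#' @param concentration Beta concentration.
#' @param seed Optional seed.
#' @return List with `alignment` (named character), `morf_scores` (named
#'   list of per-residue numeric vectors), and `truth`.
#' @export
simulate_msa_and_morfs <- function(n_organisms = 10L, width = 300L,
                                   sub_rate = 0.2, indel_rate = 0.03,
                                   morf_blocks = NULL,
                                   morf_organisms = NULL,
                                   mu_morf = 0.85, mu_background = 0.2,
                                   concentration = 30, seed = NULL) {
  if (n_organisms < 4L)
    stop("need >= 4 organisms for MoRF conservation to be testable",
         call. = FALSE)
  stopifnot(width >= 1L, sub_rate >= 0, sub_rate <= 1,
            indel_rate >= 0, indel_rate < 1)
  if (is.null(morf_blocks)) {
    s1 <- max(1L, round(0.2 * width))
    s2 <- round(0.6 * width)
    len <- 12L
    morf_blocks <- data.frame(start = c(s1, s2),
                              end = c(s1 + len - 1L, s2 + len - 1L))
    morf_blocks <- morf_blocks[morf_blocks$end <= width, , drop = FALSE]
  }
  if (NROW(morf_blocks) > 0L &&
      (any(morf_blocks$start < 1L) || any(morf_blocks$end > width)))
    stop("planted MoRF blocks outside alignment width", call. = FALSE)
  with_seed(seed, {
    org_ids <- sprintf("org%02d", seq_len(n_organisms))
    if (is.null(morf_organisms))
      morf_organisms <- org_ids[seq_len(min(6L, n_organisms))]
    ancestor <- sample(AA20, width, replace = TRUE)
    k <- concentration
    alignment <- character(n_organisms); names(alignment) <- org_ids
    morf_scores <- vector("list", n_organisms); names(morf_scores) <- org_ids
    for (o in org_ids) {
      chars <- ancestor
      subst <- stats::runif(width) < sub_rate
      chars[subst] <- sample(AA20, sum(subst), replace = TRUE)
      gone <- stats::runif(width) < indel_rate
      chars[gone] <- "-"
      if (all(chars == "-")) chars[1L] <- ancestor[1L]  # keep >= 1 residue
      alignment[[o]] <- paste(chars, collapse = "")
      non_gap <- which(chars != "-")
      Lr <- length(non_gap)
      sc <- stats::rbeta(Lr, mu_background * k, (1 - mu_background) * k)
      if (o %in% morf_organisms) {
        for (bi in seq_len(NROW(morf_blocks))) {
          cols <- morf_blocks$start[bi]:morf_blocks$end[bi]
          ridx <- which(non_gap %in% cols)
          if (length(ridx) > 0L)
            sc[ridx] <- stats::rbeta(length(ridx), mu_morf * k,
                                     (1 - mu_morf) * k)
        }
      }
      morf_scores[[o]] <- sc
    }
    list(alignment = alignment, morf_scores = morf_scores,
         truth = list(blocks = morf_blocks,
                      morf_organisms = morf_organisms))
  })
}

#' Simulate an interaction network with planted hubs
#'
#' Builds a Mediator-like interaction graph: `n_subunits` subunit nodes,
#' `n_external` candidate external partners, subunit-subunit edges with
#' probability `p_subunit_edge`, and planted hubs (the first `n_hubs`
#' subunits) topped up with distinct external partners to a degree drawn
#' in `hub_degree`; non-hub subunits receive at most `nonhub_degree[2]`
#' partners (guaranteed when their subunit-subunit degree does not already
#' exceed it).
#'
#' @param n_subunits,n_external Node counts (>= 1).
#' @param n_hubs Number of planted hub subunits.
#' @param hub_degree,nonhub_degree Integer ranges for target total degree.
#' @param p_subunit_edge Probability of each subunit-subunit edge.
#' @param n_self_loops Number of subunits given a self-loop
#'   (homodimerization).
#' @param seed Optional seed.
#' @return List with `graph` (an [interaction_graph()]) and `truth`
#'   (planted hub ids).
#' @export
simulate_network <- function(n_subunits = 30L, n_external = 300L,
                             n_hubs = 19L, hub_degree = c(10L, 40L),
                             nonhub_degree = c(0L, 9L),
                             p_subunit_edge = 0.2, n_self_loops = 1L,
                             seed = NULL) {
  stopifnot(n_subunits >= 1L, n_external >= 1L,
            n_hubs >= 0L, n_hubs <= n_subunits,
            hub_degree[1L] >= 1L, nonhub_degree[2L] < hub_degree[1L])
  with_seed(seed, {
    subs <- sprintf("Med%02d", seq_len(n_subunits))
    ext <- sprintf("EXT%04d", seq_len(n_external))
    hubs <- subs[seq_len(n_hubs)]
    a <- character(0); b <- character(0)
    if (n_subunits > 1L) {
      pairs <- utils::combn(subs, 2L)
      keep <- stats::runif(ncol(pairs)) < p_subunit_edge
      a <- pairs[1L, keep]; b <- pairs[2L, keep]
    }
    deg <- table(factor(c(a, b), levels = subs))
    for (s in subs) {
      is_hub <- s %in% hubs
      rng <- if (is_hub) hub_degree else nonhub_degree
      target <- if (rng[1L] >= rng[2L]) rng[1L]
                else sample(seq.int(rng[1L], rng[2L]), 1L)
      need <- max(0L, target - as.integer(deg[[s]]))
      need <- min(need, n_external)
      if (need > 0L) {
        partners <- sample(ext, need)
        a <- c(a, rep(s, need)); b <- c(b, partners)
      }
    }
    if (n_self_loops > 0L) {
      sl <- subs[seq_len(min(n_self_loops, n_subunits))]
      a <- c(a, sl); b <- c(b, sl)
    }
    list(graph = interaction_graph(a, b, subunit_ids = subs),
         truth = list(hubs = hubs))
  })
}

#' Write a complete simulated study to disk
#'
#' Emits exactly the file set [run_pipeline()] reads: per-profile score
#' tables, the manifest, the organism table, a PTM site table, an aligned
#' FASTA plus MoRF score table for one subunit, and an interaction edge
#' list. All randomness derives from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if missing).
#' @param msa_args,network_args Optional argument lists overriding the
#'   [simulate_msa_and_morfs()] / [simulate_network()] defaults.
#' @return Named list of file paths (manifest, organisms, ptm, msa, morf,
#'   edges), invisibly.
#' @export
write_simulated_study <- function(config, dir,
                                  msa_args = list(),
                                  network_args = list()) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(file.path(dir, "scores"), recursive = TRUE,
             showWarnings = FALSE)
  sim <- simulate_profiles(config)
  man <- list(); ptm_rows <- list()
  for (key in names(sim$profiles)) {
    p <- sim$profiles[[key]]
    rel <- file.path("scores", paste0(gsub("[^A-Za-z0-9_.-]", "_", key),
                                      ".tsv"))
    write_score_table(p, file.path(dir, rel))
    man[[key]] <- data.frame(organism_id = p$organism_id,
                             kingdom = p$kingdom,
                             subunit_id = p$subunit_id,
                             score_path = rel, stringsAsFactors = FALSE)
    tr <- simulate_ptm_track(p, sim$truth$blocks[[key]],
                             rate = config$ptm_rate,
                             idr_odds = config$ptm_idr_odds,
                             seed = child_seed(config$seed,
                                               paste0("ptm|", key)))
    if (nrow(tr) > 0L)
      ptm_rows[[key]] <- data.frame(organism_id = p$organism_id,
                                    subunit_id = p$subunit_id,
                                    position = tr$position,
                                    ptm_type = tr$ptm_type,
                                    stringsAsFactors = FALSE)
  }
  paths <- list(manifest = file.path(dir, "manifest.tsv"),
                organisms = file.path(dir, "organisms.tsv"),
                ptm = file.path(dir, "ptm.tsv"),
                msa = file.path(dir, "msa_Med15.fasta"),
                morf = file.path(dir, "morf.tsv"),
                edges = file.path(dir, "edges.tsv"))
  write_tsv(do.call(rbind, c(man, list(make.row.names = FALSE))),
            paths$manifest)
  write_tsv(sim$organisms, paths$organisms)
  ptm_df <- if (length(ptm_rows) > 0L)
    do.call(rbind, c(ptm_rows, list(make.row.names = FALSE)))
  else
    data.frame(organism_id = character(0), subunit_id = character(0),
               position = integer(0), ptm_type = character(0))
  write_tsv(ptm_df, paths$ptm)

  msa_args$seed <- msa_args$seed %||% child_seed(config$seed, "msa")
  msa <- do.call(simulate_msa_and_morfs, msa_args)
  aa <- Biostrings::AAStringSet(msa$alignment)
  Biostrings::writeXStringSet(aa, paths$msa)
  morf_rows <- do.call(rbind, lapply(names(msa$morf_scores), function(o) {
    sc <- msa$morf_scores[[o]]
    data.frame(organism_id = o, subunit_id = "Med15",
               position = seq_along(sc), score = sc,
               stringsAsFactors = FALSE)
  }))
  write_tsv(morf_rows, paths$morf)

  network_args$seed <- network_args$seed %||% child_seed(config$seed, "net")
  net <- do.call(simulate_network, network_args)
  write_edges(net$graph, paths$edges)
  writeLines(net$graph$subunit_ids, file.path(dir, "subunit_nodes.txt"))
  paths$subunit_nodes <- file.path(dir, "subunit_nodes.txt")
  invisible(paths)
}
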