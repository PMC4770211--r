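#' Pipeline run configuration
#'
#' Bundles the input manifest, analysis thresholds (defaults are the
#' study's stated values: disorder 0.5, IDR minimum 30 residues with
#' 3-residue gaps, conservation 70%/50%, MoRF minimum 5 residues at 0.5,
#' hub thresholds 10 and 5, hotspot window 30 with density band
#' 0.1-0.3, alpha 0.05), the distance policy, the tree-cutting mode, and
#' the output directory.
#'
#' @param manifest Path to a manifest TSV with columns `organism_id`,
#'   `kingdom`, `subunit_id`, `score_path` (paths relative to the
#'   manifest's directory or absolute).
#' @param outdir Output directory for the report bundle.
#' @param disorder_threshold,idr_min,idr_gap IDR-calling parameters.
#' @param conserved_pct,moderate_pct Conservation class thresholds (%).
#' @param morf_min,morf_threshold MoRF-calling parameters.
#' @param hub_threshold,subunit_hub_threshold Hub classification counts.
#' @param hotspot_window,hotspot_min,hotspot_max PTM hotspot parameters.
#' @param alpha Mann-Whitney significance level.
#' @param distance_policy `"shared_only"` or `"shared_rescaled"`.
#' @param cut_mode `"length_threshold"` or `"k_groups"`.
#' @param k,tau Cutting parameters (see [cut_groups()]).
#' @param ptm_path,morf_path,msa_path,edges_path,subunit_nodes_path
#'   Optional auxiliary inputs; stages lacking input are skipped with a
#'   warning, never a crash.
#' @param junction_window Junction-MoRF boundary half-width.
#' @param seed Seed echoed into the run log (the analysis itself is
#'   deterministic).
#' @return Object of class `run_config`.
#' @export
run_config <- function(manifest, outdir,
                       disorder_threshold = 0.5,
                       idr_min = 30L, idr_gap = 3L,
                       conserved_pct = 70, moderate_pct = 50,
                       morf_min = 5L, morf_threshold = 0.5,
                       hub_threshold = 10L, subunit_hub_threshold = 5L,
                       hotspot_window = 30L,
                       hotspot_min = 0.1, hotspot_max = 0.3,
                       alpha = 0.05,
                       distance_policy = "shared_only",
                       cut_mode = "length_threshold",
                       k = 4L, tau = 8,
                       ptm_path = NULL, morf_path = NULL,
                       msa_path = NULL, edges_path = NULL,
                       subunit_nodes_path = NULL,
                       junction_window = 10L,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML config path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config keys: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  base <- dirname(normalizePath(path))
  for (key in c("manifest", "outdir", "ptm_path", "morf_path", "msa_path",
                "edges_path", "subunit_nodes_path")) {
    v <- vals[[key]]
    if (!is.null(v) && !grepl("^/", v)) vals[[key]] <- file.path(base, v)
  }
  do.call(run_config, vals)
}

#' Validate a run configuration
#'
#' @param config A [run_config()].
#' @return Character vector of violations; empty when all invariants hold.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  chk(is.numeric(config$disorder_threshold) &&
        config$disorder_threshold > 0 && config$disorder_threshold < 1,
      "disorder_threshold must lie in (0, 1)")
  chk(config$idr_min >= 1, "idr_min must be >= 1")
  chk(config$idr_gap >= 0, "idr_gap must be >= 0")
  chk(config$conserved_pct >= 0 && config$conserved_pct <= 100,
      "conserved_pct must lie in [0, 100]")
  chk(config$moderate_pct >= 0 &&
        config$moderate_pct <= config$conserved_pct,
      "moderate_pct must lie in [0, conserved_pct]")
  chk(config$morf_min >= 1, "morf_min must be >= 1")
  chk(config$morf_threshold > 0 && config$morf_threshold < 1,
      "morf_threshold must lie in (0, 1)")
  chk(config$hub_threshold >= 1, "hub_threshold must be >= 1")
  chk(config$subunit_hub_threshold >= 1,
      "subunit_hub_threshold must be >= 1")
  chk(config$hotspot_window >= 1, "hotspot_window must be >= 1")
  chk(config$hotspot_min >= 0 && config$hotspot_min <= config$hotspot_max &&
        config$hotspot_max <= 1,
      "hotspot band must satisfy 0 <= min <= max <= 1")
  chk(config$alpha > 0 && config$alpha < 1, "alpha must lie in (0, 1)")
  chk(config$distance_policy %in% c("shared_only", "shared_rescaled"),
      "distance_policy must be shared_only or shared_rescaled")
  chk(config$cut_mode %in% c("length_threshold", "k_groups"),
      "cut_mode must be length_threshold or k_groups")
  chk(config$k >= 1, "k must be >= 1")
  chk(is.numeric(config$tau) && config$tau > 0, "tau must be > 0")
  chk(config$junction_window >= 0, "junction_window must be >= 0")
  v
}

resolve_path <- function(p, base) {
  if (grepl("^/", p)) p else file.path(base, p)
}

#' Run the full disorder-evolution pipeline
#'
#' Stage order: profiles, IDR calling, conservation and the disorder
#' matrix, clustering, kingdom statistics, PTM analysis, MoRF analysis,
#' hub classification. Writes `averages.tsv`, `idr_segments.tsv`,
#' `idr_conservation.tsv`, `distance.phylip`, `tree.nwk`, `groups.tsv`,
#' `kingdom_stats.tsv`, `ptm_report.tsv`, `ptm_hotspots.tsv`,
#' `morf_report.tsv`, `hubs.tsv`, and `run_log.txt` (config echo plus
#' package version; no timestamps, so identical runs are byte-identical).
#' Stages whose inputs are absent are skipped with a warning. The
#' pipeline adds no computation of its own: every reported number is the
#' output of the corresponding module function.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the written report paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bad <- validate_config(config)
  if (length(bad) > 0L)
    stop(paste(c("invalid configuration:", bad), collapse = "\n  "),
         call. = FALSE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  log_lines <- c(sprintf("medidr %s",
                         as.character(utils::packageVersion("medidr"))),
                 "effective configuration:")
  ## the log echoes every analysis setting; file locations are not
  ## settings, and leaving them out keeps bundles byte-identical across
  ## input/output locations
  path_keys <- c("manifest", "outdir", "ptm_path", "morf_path", "msa_path",
                 "edges_path", "subunit_nodes_path")
  for (nm in setdiff(sort(names(unclass(config))), path_keys)) {
    val <- config[[nm]]
    log_lines <- c(log_lines, sprintf("  %s = %s", nm,
                                      paste(format(val), collapse = ", ")))
  }

  ## --- profiles -------------------------------------------------------
  man <- read_tsv(config$manifest)
  need <- c("organism_id", "kingdom", "subunit_id", "score_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns organism_id, kingdom, subunit_id, score_path",
         call. = FALSE)
  base <- dirname(normalizePath(config$manifest))
  profiles <- lapply(seq_len(nrow(man)), function(i)
    read_score_table(resolve_path(man$score_path[i], base),
                     man$organism_id[i], man$subunit_id[i],
                     man$kingdom[i]))
  names(profiles) <- paste(man$organism_id, man$subunit_id, sep = "|")

  averages <- data.frame(
    organism_id = man$organism_id, kingdom = man$kingdom,
    subunit_id = man$subunit_id,
    length = vapply(profiles, function(p) nchar(p$sequence), 0L),
    avg_disorder = vapply(profiles, average_disorder, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  out$averages <- write_tsv(averages, file.path(config$outdir,
                                                "averages.tsv"))

  ## --- IDR segments ---------------------------------------------------
  segs <- do.call(rbind, lapply(profiles, idr_segments,
                                threshold = config$disorder_threshold,
                                min_len = config$idr_min,
                                max_gap = config$idr_gap))
  rownames(segs) <- NULL
  out$idr_segments <- write_tsv(segs, file.path(config$outdir,
                                                "idr_segments.tsv"))

  ## --- conservation ---------------------------------------------------
  cons <- list()
  for (kng in intersect(c("metazoa", "plantae", "fungi", "other"),
                        unique(man$kingdom))) {
    man_k <- man[man$kingdom == kng, , drop = FALSE]
    for (sub in unique(man_k$subunit_id)) {
      orgs <- man_k$organism_id[man_k$subunit_id == sub]
      presence <- lapply(orgs, function(o) {
        s <- segs[segs$organism_id == o & segs$subunit_id == sub, ,
                  drop = FALSE]
        unique(s$region)
      })
      names(presence) <- orgs
      cons[[paste(kng, sub)]] <- classify_conservation(
        presence, kingdom = kng, subunit_id = sub,
        high = config$conserved_pct, moderate = config$moderate_pct)
    }
  }
  cons <- do.call(rbind, c(cons, list(make.row.names = FALSE)))
  out$idr_conservation <- write_tsv(cons, file.path(config$outdir,
                                                    "idr_conservation.tsv"))

  ## --- clustering -----------------------------------------------------
  if (length(unique(man$organism_id)) >= 2L) {
    mat <- build_disorder_matrix(profiles)
    d <- disorder_distance_matrix(mat, policy = config$distance_policy)
    out$distance <- write_phylip(d, file.path(config$outdir,
                                              "distance.phylip"))
    tree <- nj_tree(d)
    ape::write.tree(tree, file.path(config$outdir, "tree.nwk"))
    out$tree <- file.path(config$outdir, "tree.nwk")
    groups <- if (config$cut_mode == "k_groups")
      cut_groups(tree, "k_groups", k = config$k)
    else
      cut_groups(tree, "length_threshold", tau = config$tau)
    out$groups <- write_tsv(groups_table(groups),
                            file.path(config$outdir, "groups.tsv"))
  } else {
    warning("fewer than 2 organisms: clustering skipped", call. = FALSE)
    log_lines <- c(log_lines, "WARN clustering skipped (< 2 organisms)")
  }

  ## --- kingdom statistics --------------------------------------------
  stats_tab <- kingdom_comparison(averages, alpha = config$alpha)
  out$kingdom_stats <- write_tsv(stats_tab,
                                 file.path(config$outdir,
                                           "kingdom_stats.tsv"))

  ## --- PTM ------------------------------------------------------------
  if (!is.null(config$ptm_path) && file.exists(config$ptm_path)) {
    ptm <- read_ptm_table(config$ptm_path)
    rep_rows <- list(); hot_rows <- list()
    for (key in unique(paste(ptm$organism_id, ptm$subunit_id, sep = "|"))) {
      p <- profiles[[key]]
      if (is.null(p)) next
      pr <- ptm[paste(ptm$organism_id, ptm$subunit_id, sep = "|") == key, ,
                drop = FALSE]
      L <- nchar(p$sequence)
      track <- ptm_track(pr$position, pr$ptm_type, L,
                         p$organism_id, p$subunit_id)
      idrs <- segs[segs$organism_id == p$organism_id &
                     segs$subunit_id == p$subunit_id, , drop = FALSE]
      ds <- disorder_at_sites(p, track)
      rep_rows[[key]] <- data.frame(
        organism_id = p$organism_id, subunit_id = p$subunit_id,
        n_sites = nrow(track),
        fraction_in_idr = fraction_in_idr(track, idrs),
        mean_disorder_ptm = ds$mean_ptm,
        mean_disorder_non_ptm = ds$mean_non_ptm,
        stringsAsFactors = FALSE)
      hs <- find_hotspots(track, L, window = config$hotspot_window,
                          min_density = config$hotspot_min,
                          max_density = config$hotspot_max)
      if (nrow(hs) > 0L)
        hot_rows[[key]] <- cbind(data.frame(
          organism_id = p$organism_id, subunit_id = p$subunit_id,
          stringsAsFactors = FALSE), hs)
    }
    out$ptm_report <- write_tsv(
      do.call(rbind, c(rep_rows, list(make.row.names = FALSE))),
      file.path(config$outdir, "ptm_report.tsv"))
    hot_df <- if (length(hot_rows) > 0L)
      do.call(rbind, c(hot_rows, list(make.row.names = FALSE)))
    else data.frame(organism_id = character(0), subunit_id = character(0),
                    start = integer(0), end = integer(0),
                    density = numeric(0), band = character(0))
    out$ptm_hotspots <- write_tsv(hot_df, file.path(config$outdir,
                                                    "ptm_hotspots.tsv"))
  } else {
    warning("no PTM table supplied: PTM stages skipped", call. = FALSE)
    log_lines <- c(log_lines, "WARN PTM stages skipped (no input)")
  }

  ## --- MoRF -----------------------------------------------------------
  if (!is.null(config$morf_path) && file.exists(config$morf_path)) {
    morf <- read_tsv(config$morf_path)
    morf_rows <- list()
    coverage <- list()
    msa <- if (!is.null(config$msa_path) && file.exists(config$msa_path))
      read_msa(config$msa_path) else NULL
    for (key in unique(paste(morf$organism_id, morf$subunit_id,
                             sep = "|"))) {
      mr <- morf[paste(morf$organism_id, morf$subunit_id, sep = "|") == key,
                 , drop = FALSE]
      mr <- mr[order(mr$position), , drop = FALSE]
      segs_m <- call_morfs(mr$score, min_len = config$morf_min,
                           threshold = config$morf_threshold)
      org <- mr$organism_id[1L]; sub <- mr$subunit_id[1L]
      idrs <- segs[segs$organism_id == org & segs$subunit_id == sub, ,
                   drop = FALSE]
      segs_m <- junction_morfs(segs_m, idrs, w = config$junction_window)
      if (nrow(segs_m) > 0L)
        morf_rows[[key]] <- cbind(data.frame(organism_id = org,
                                             subunit_id = sub,
                                             stringsAsFactors = FALSE),
                                  segs_m)
      if (!is.null(msa) && org %in% names(msa)) {
        cov <- integer(0)
        for (i in seq_len(nrow(segs_m)))
          cov <- c(cov, map_segment_to_columns(segs_m$start[i],
                                               segs_m$end[i], msa[[org]]))
        coverage[[org]] <- cov
      }
    }
    morf_df <- if (length(morf_rows) > 0L)
      do.call(rbind, c(morf_rows, list(make.row.names = FALSE)))
    else data.frame(organism_id = character(0), subunit_id = character(0),
                    start = integer(0), end = integer(0),
                    length = integer(0), is_junction = logical(0))
    out$morf_report <- write_tsv(morf_df, file.path(config$outdir,
                                                    "morf_report.tsv"))
    if (length(coverage) >= 4L) {
      cons_m <- conserved_morf_regions(coverage,
                                       width = nchar(msa[[1L]]),
                                       min_organisms = 4L,
                                       min_run = config$morf_min)
      cons_m$supporting <- vapply(cons_m$supporting, paste,
                                  "", collapse = ",")
      out$morf_conserved <- write_tsv(cons_m,
                                      file.path(config$outdir,
                                                "morf_conserved.tsv"))
    }
  } else {
    warning("no MoRF table supplied: MoRF stages skipped", call. = FALSE)
    log_lines <- c(log_lines, "WARN MoRF stages skipped (no input)")
  }

  ## --- hubs -----------------------------------------------------------
  if (!is.null(config$edges_path) && file.exists(config$edges_path)) {
    sub_ids <- if (!is.null(config$subunit_nodes_path) &&
                   file.exists(config$subunit_nodes_path))
      readLines(config$subunit_nodes_path, warn = FALSE)
    else character(0)
    graph <- read_edges(config$edges_path, subunit_ids = sub_ids)
    out$hubs <- write_tsv(classify_hubs(graph,
                                        config$hub_threshold,
                                        config$subunit_hub_threshold),
                          file.path(config$outdir, "hubs.tsv"))
  } else {
    warning("no edge list supplied: hub stage skipped", call. = FALSE)
    log_lines <- c(log_lines, "WARN hub stage skipped (no input)")
  }

  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  out$run_log <- file.path(config$outdir, "run_log.txt")
  invisible(out)
}
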