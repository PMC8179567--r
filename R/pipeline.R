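# End-to-end orchestration of the design protocol: anchor -> poly-Gly
# extension -> closure sampling against the target -> energy and
# hydrogen-bond filters -> Monte-Carlo sequence design -> interface
# metrics -> ranking -> optional landscape validation of the top designs.

#' Filter configuration for sampled backbones
#'
#' @param max_energy Keep solutions with total E at or below this (default
#'   0: "high-energy structures (E > 0) discarded").
#' @param min_backbone_hbonds Minimum intramolecular backbone hydrogen
#'   bonds (default 2: "no or very few" filtered).
#' @param clash_factor Hard-sphere screen threshold used during sampling.
#' @param keep_top_k Designs carried forward after ranking (>= 1).
#' @return A `FilterConfig` list.
#' @export
filter_config <- function(max_energy = 0, min_backbone_hbonds = 2,
                          clash_factor = 0.6, keep_top_k = 5) {
  if (keep_top_k < 1) stop("keep_top_k must be >= 1")
  structure(list(max_energy = max_energy,
                 min_backbone_hbonds = min_backbone_hbonds,
                 clash_factor = clash_factor, keep_top_k = keep_top_k),
            class = "FilterConfig")
}

#' Apply the energy and hydrogen-bond filters to closure solutions
#'
#' Keeps solutions with total energy at or below `max_energy` (boundary
#' kept) and at least `min_backbone_hbonds` intramolecular backbone
#' hydrogen bonds. Order is preserved; the output is a subset of the
#' input.
#'
#' @param solutions List of scored `ClosureSolution`s (from
#'   [sample_closed_backbones()]).
#' @param cfg A `FilterConfig`.
#' @return Filtered list; attribute `"counts"` reports rejections per
#'   criterion.
#' @export
apply_filters <- function(solutions, cfg = filter_config()) {
  if (length(solutions) == 0) {
    return(structure(list(), counts = c(input = 0, e_rejected = 0,
                                        hbond_rejected = 0, kept = 0)))
  }
  e_rej <- 0; h_rej <- 0
  keep <- logical(length(solutions))
  for (i in seq_along(solutions)) {
    s <- solutions[[i]]
    e <- if (!is.null(s$energy)) s$energy$total else
      stop("solutions must be scored before filtering")
    if (e > cfg$max_energy) { e_rej <- e_rej + 1; next }
    if (count_backbone_hbonds(s$pose) < cfg$min_backbone_hbonds) {
      h_rej <- h_rej + 1; next
    }
    keep[i] <- TRUE
  }
  structure(solutions[keep],
            counts = c(input = length(solutions), e_rejected = e_rej,
                       hbond_rejected = h_rej, kept = sum(keep)))
}

#' Assemble a design specification
#'
#' @param target Path to a target PDB file, or a `TargetStructure`.
#' @param hotspot_mode `"extract"` (from a bound partner chain) or
#'   `"scan"` (rotamer-scan placement on a surface site).
#' @param partner_chain,partner_res For `"extract"`.
#' @param identity,site,normal For `"scan"`.
#' @param ring_sizes Integer vector within \[7, 12\].
#' @param n_attempts Closure sampling attempts per ring size.
#' @param seed Integer seed (explicit: no wall-clock seeding).
#' @param filters A `FilterConfig`.
#' @param palette A `DesignPalette`.
#' @param schedule An `MCSchedule` (its seed is derived from `seed`).
#' @param landscape_samples If > 0, run landscape validation with this
#'   many samples on the ranked designs.
#' @param output_dir Optional output directory for scorefile/PDBs.
#' @return A `DesignSpec` list.
#' @export
design_spec <- function(target, hotspot_mode = c("extract", "scan"),
                        partner_chain = NULL, partner_res = NULL,
                        identity = "TRP", site = NULL, normal = NULL,
                        ring_sizes = c(8, 9, 10), n_attempts = 1000,
                        seed = 1, filters = filter_config(),
                        palette = design_palette(),
                        schedule = mc_schedule(n_moves = 600),
                        landscape_samples = 0, output_dir = NULL) {
  hotspot_mode <- match.arg(hotspot_mode)
  if (any(ring_sizes < 7 | ring_sizes > 12)) {
    stop("ring sizes must be within [7, 12]")
  }
  structure(list(target = target, hotspot_mode = hotspot_mode,
                 partner_chain = partner_chain, partner_res = partner_res,
                 identity = identity, site = site, normal = normal,
                 ring_sizes = as.integer(ring_sizes),
                 n_attempts = n_attempts, seed = seed, filters = filters,
                 palette = palette, schedule = schedule,
                 landscape_samples = landscape_samples,
                 output_dir = output_dir),
            class = "DesignSpec")
}

#' Run the full design pipeline
#'
#' Executes anchor selection, poly-Gly closure sampling against the
#' target, the E/H-bond filter cascade, Monte-Carlo sequence design of
#' the surviving backbones, interface metrics, ranking, and (optionally)
#' landscape validation. Fully reproducible under `spec$seed`; per-stage
#' candidate counts are returned and never increase along the cascade.
#'
#' @param spec A `DesignSpec`.
#' @param verbose Print per-stage counters.
#' @return List with `records` (ranked `DesignRecord`s), `counts`
#'   (per-stage), `verdicts` (landscape verdicts if requested), `paths`
#'   (written files if `output_dir` set).
#' @export
run_design <- function(spec, verbose = FALSE) {
  target <- if (inherits(spec$target, "TargetStructure")) spec$target
            else read_pdb(spec$target)
  say <- function(...) if (verbose) message(sprintf(...))

  if (spec$hotspot_mode == "extract") {
    if (is.null(spec$partner_chain) || is.null(spec$partner_res)) {
      stop("extract mode needs partner_chain and partner_res")
    }
    anchor <- extract_hotspot(target, spec$partner_chain,
                              spec$partner_res)
    target <- filter_chains(target,
                            setdiff(unique(target$atoms$chain),
                                    spec$partner_chain))
  } else {
    if (is.null(spec$site) || is.null(spec$normal)) {
      stop("scan mode needs site and normal")
    }
    anchor <- rotamer_scan_place(target, spec$identity, spec$site,
                                 spec$normal,
                                 clash_factor = spec$filters$clash_factor)
  }
  say("stage hotspot: anchor %s (%s)", anchor$identity, anchor$source)

  all_sols <- list()
  counts <- list()
  for (nr in spec$ring_sizes) {
    sols <- sample_closed_backbones(
      anchor, target, n_residues = nr, n_attempts = spec$n_attempts,
      seed = spec$seed + 1000 * match(nr, spec$ring_sizes),
      clash_factor = spec$filters$clash_factor)
    st <- attr(sols, "stats")
    counts[[as.character(nr)]] <- st
    say("stage sampling (n=%d): %d attempts, %d closed, %d clash-rejected, %d kept",
        nr, st["attempts"], st["closed"], st["clash_rejected"],
        st["kept"])
    all_sols <- c(all_sols, sols)
  }
  filtered <- apply_filters(all_sols, spec$filters)
  fc <- attr(filtered, "counts")
  say("stage filters: %d in, %d E-rejected, %d hbond-rejected, %d kept",
      fc["input"], fc["e_rejected"], fc["hbond_rejected"], fc["kept"])

  # design the best backbones (by sampled energy), up to keep_top_k
  if (length(filtered) > 0) {
    e <- vapply(filtered, function(s) s$energy$total, numeric(1))
    filtered <- filtered[order(e)]
    filtered <- filtered[seq_len(min(length(filtered),
                                     spec$filters$keep_top_k))]
  }
  records <- list()
  for (i in seq_along(filtered)) {
    sch <- spec$schedule
    sch$seed <- spec$seed + 7000 + i
    rec <- design(filtered[[i]]$pose, target, spec$palette, sch)
    rec$ring_size <- pose_length(rec$pose)
    rec$source_attempt <- filtered[[i]]$attempt
    records[[length(records) + 1]] <- rec
  }
  say("stage design: %d records", length(records))
  if (length(records) == 0) {
    warning("zero survivors: empty outputs")
    return(list(records = list(), counts = counts,
                filter_counts = fc, verdicts = NULL, paths = NULL))
  }
  records <- rank_designs(records)

  verdicts <- NULL
  if (spec$landscape_samples > 0) {
    verdicts <- lapply(records, function(r) {
      pts <- predict_landscape(r, n_samples = spec$landscape_samples,
                               seed = spec$seed + 9000)
      funnel_verdict(pts)
    })
  }

  paths <- NULL
  if (!is.null(spec$output_dir)) {
    paths <- write_design_outputs(records, spec, counts, fc, verdicts)
  }
  list(records = records, counts = counts, filter_counts = fc,
       verdicts = verdicts, paths = paths)
}

#' Scorefile table for a list of design records
#'
#' One row per design: sequence (D residues lower case), ring size,
#' per-term energies, interface metrics.
#'
#' @param records List of `DesignRecord`s.
#' @return Data frame in fixed column order.
#' @export
scorefile_table <- function(records) {
  do.call(rbind, lapply(seq_along(records), function(i) {
    r <- records[[i]]
    data.frame(
      rank = i, sequence = design_sequence_string(r),
      ring_size = if (!is.null(r$ring_size)) r$ring_size
                  else pose_length(r$pose),
      total_energy = r$energy$total, steric = r$energy$steric,
      hbond = r$energy$hbond, rama = r$energy$rama,
      composition = r$energy$composition,
      interaction_energy = r$interface$interaction_energy,
      buried_sasa = r$interface$buried_sasa, sc = r$interface$sc,
      inter_hbonds = r$interface$inter_hbond_count,
      intra_hbonds = r$interface$intra_hbond_count,
      stringsAsFactors = FALSE)
  }))
}

write_design_outputs <- function(records, spec, counts, fc, verdicts) {
  dir.create(spec$output_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- scorefile_table(records)
  score_path <- file.path(spec$output_dir, "scorefile.tsv")
  utils::write.table(tab, score_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pdb_paths <- character(0)
  for (i in seq_along(records)) {
    p <- file.path(spec$output_dir, sprintf("design_%03d.pdb", i))
    write_pdb(records[[i]]$pose, p)
    pdb_paths <- c(pdb_paths, p)
  }
  cfg_path <- file.path(spec$output_dir, "run_config.yaml")
  write_design_config(spec, cfg_path)
  log_path <- file.path(spec$output_dir, "counts.yaml")
  yaml::write_yaml(list(sampling = lapply(counts, as.list),
                        filters = as.list(fc)), log_path)
  out <- list(scorefile = score_path, pdbs = pdb_paths,
              config = cfg_path, log = log_path)
  if (!is.null(verdicts)) {
    v_path <- file.path(spec$output_dir, "verdicts.yaml")
    yaml::write_yaml(lapply(verdicts, unclass), v_path)
    out$verdicts <- v_path
  }
  out
}

#' Write a design spec to a YAML config file
#' @param spec A `DesignSpec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_config <- function(spec, path) {
  x <- unclass(spec)
  x$target <- if (inherits(spec$target, "TargetStructure")) {
    spec$target$source
  } else spec$target
  x$filters <- unclass(spec$filters)
  x$palette <- unclass(spec$palette)
  x$schedule <- unclass(spec$schedule)
  x$output_dir <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a design spec from a YAML config file
#'
#' Inverse of [write_design_config()]: `read(write(spec))` reproduces the
#' spec (the target is referenced by path).
#'
#' @param path Config file path.
#' @return A `DesignSpec`.
#' @export
read_design_config <- function(path) {
  x <- yaml::read_yaml(path)
  design_spec(
    target = x$target, hotspot_mode = x$hotspot_mode,
    partner_chain = x$partner_chain, partner_res = x$partner_res,
    identity = x$identity, site = unlist(x$site),
    normal = unlist(x$normal), ring_sizes = unlist(x$ring_sizes),
    n_attempts = x$n_attempts, seed = x$seed,
    filters = do.call(filter_config, x$filters),
    palette = do.call(design_palette, x$palette),
    schedule = do.call(mc_schedule, x$schedule),
    landscape_samples = x$landscape_samples)
}
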