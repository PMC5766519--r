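# Study-design enumeration, time windowing and per-system orchestration
# of the full assay, with CSV reporting.

#' Define a simulation study design
#'
#' The default design reproduces the study matrix: five receptor isoforms
#' (wild type plus the four resistance variants), each simulated apo and
#' estrogen-bound in the agonist conformation and with three antagonists
#' in the antagonist conformation, 500 ns of production each.
#'
#' @param isoforms receptor isoforms.
#' @param agonist_ligands ligands simulated in the agonist conformation.
#' @param antagonist_ligands ligands simulated in the antagonist
#'   conformation.
#' @param length_ns production length per system, ns.
#' @return Object of class `system_design`.
#' @export
system_design <- function(isoforms = c("WT", "L536Q", "Y537S", "Y537N",
                                       "D538G"),
                          agonist_ligands = c("apo", "EST"),
                          antagonist_ligands = c("END", "AZD-9496", "FULV"),
                          length_ns = 500) {
  if (length(isoforms) == 0) stop("need at least one isoform")
  if (length_ns <= 0) stop("length_ns must be > 0")
  structure(list(isoforms = isoforms,
                 agonist_ligands = agonist_ligands,
                 antagonist_ligands = antagonist_ligands,
                 length_ns = length_ns),
            class = "system_design")
}

#' Enumerate every system of a study design
#'
#' Deterministic isoform-major ordering (agonist-state ligands before
#' antagonist-state ligands). The default design enumerates 25 systems
#' for a cumulative 12,500 ns (12.5 us) of simulation.
#'
#' @param design a [system_design].
#' @return list with `systems` (data.frame `system_id`, `isoform`,
#'   `state`, `ligand`, `length_ns`), `n_systems` and
#'   `cumulative_time_ns`.
#' @export
enumerate_design <- function(design = system_design()) {
  stopifnot(inherits(design, "system_design"))
  rows <- list()
  for (iso in design$isoforms) {
    for (lig in design$agonist_ligands)
      rows[[length(rows) + 1]] <- data.frame(isoform = iso,
                                             state = "agonist",
                                             ligand = lig,
                                             stringsAsFactors = FALSE)
    for (lig in design$antagonist_ligands)
      rows[[length(rows) + 1]] <- data.frame(isoform = iso,
                                             state = "antagonist",
                                             ligand = lig,
                                             stringsAsFactors = FALSE)
  }
  systems <- do.call(rbind, rows)
  systems$system_id <- paste(systems$isoform, systems$ligand, sep = "/")
  if (anyDuplicated(systems$system_id))
    stop("duplicate system descriptor: ",
         systems$system_id[duplicated(systems$system_id)][1])
  systems$length_ns <- design$length_ns
  systems <- systems[, c("system_id", "isoform", "state", "ligand",
                         "length_ns")]
  list(systems = systems, n_systems = nrow(systems),
       cumulative_time_ns = nrow(systems) * design$length_ns)
}

#' Restrict a trajectory to its analysis window
#'
#' In `"absolute"` mode, frames with time `>= value` (ns) are retained --
#' the form of "analyse the last 300 ns of a 500 ns run" (start at
#' 200 ns). In `"fraction"` mode the last `value` fraction of frames is
#' retained; the default analysis window elsewhere in the package is the
#' final 60% of frames, the length-relative equivalent.
#'
#' @param traj a [trajectory].
#' @param mode `"fraction"` or `"absolute"`.
#' @param value fraction in (0, 1], or a start time in ns.
#' @return The windowed [trajectory]; attribute `window` records the rule.
#' @export
apply_window <- function(traj, mode = c("fraction", "absolute"), value) {
  stopifnot(inherits(traj, "trajectory"))
  mode <- match.arg(mode)
  if (mode == "fraction") {
    if (value <= 0 || value > 1) stop("fraction must be in (0, 1]")
    n_keep <- round(value * traj$n_frames)
    if (n_keep < 1) stop("window retains no frames")
    keep <- seq(traj$n_frames - n_keep + 1, traj$n_frames)
  } else {
    keep <- which(traj$times >= value)
    if (length(keep) == 0)
      stop("window start ", value, " ns is beyond the trajectory span (",
           traj$times[1], "-", traj$times[traj$n_frames], " ns)")
  }
  out <- subset_frames(traj, keep)
  attr(out, "window") <- list(mode = mode, value = value,
                              n_kept = length(keep))
  out
}

default_assay_params <- function() {
  list(threshold = 0.6,
       activation_threshold = 4,
       intermediate_lower = 2,
       rmsd_cutoff = 2.75,
       hbond = list(d_max = 3.3, theta_max = 35),
       window = list(mode = "fraction", value = 0.6),
       helix_segment = c(527, 552))
}

merge_params <- function(user) {
  p <- default_assay_params()
  for (nm in names(user)) {
    if (nm == "hbond" || nm == "window") {
      for (k in names(user[[nm]])) p[[nm]][[k]] <- user[[nm]][[k]]
    } else p[[nm]] <- user[[nm]]
  }
  p
}

validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$systems) || length(config$systems) == 0)
    stop("config must declare at least one system")
  for (sys in config$systems) {
    if (is.null(sys$id)) stop("every system needs an `id`")
    has_files <- !is.null(sys$topology) && !is.null(sys$trajectory)
    has_synth <- !is.null(sys$synthetic)
    if (!has_files && !has_synth)
      stop("system '", sys$id,
           "' must give either topology+trajectory paths or a synthetic spec")
    if (has_files && is.null(sys$dt_ns))
      stop("system '", sys$id, "' with trajectory files needs dt_ns")
  }
  ids <- vapply(config$systems, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate system id: ", ids[duplicated(ids)][1])
  config
}

config_to_spec <- function(s) {
  args <- s$synthetic
  rc <- args$region_correlations
  if (!is.null(rc)) args$region_correlations <- rc
  do.call(synthetic_spec, args)
}

analyse_system <- function(sys, params, scheme) {
  if (!is.null(sys$synthetic)) {
    spec <- config_to_spec(sys)
    gen <- generate_trajectory(spec, scheme = scheme)
    top <- gen$topology; traj <- gen$trajectory
    isoform <- spec$isoform
  } else {
    top <- load_topology(sys$topology)
    traj <- load_trajectory(sys$trajectory, top, dt_ns = sys$dt_ns)
    isoform <- if (!is.null(sys$isoform)) sys$isoform else NA_character_
  }
  win <- apply_window(traj, mode = params$window$mode,
                      value = params$window$value)
  ca <- select_atoms(top, name = "CA")
  aligned <- superpose_to_mean(win, sel = ca)$trajectory
  cm <- compute_dccm(aligned, top, sel = ca)
  chains <- unique(top$atoms$chain)

  profiles <- list(); region_maps <- list(); clusters <- list()
  helicity <- list(); rmsf_tabs <- list()
  has_backbone <- all(c("N", "H", "O") %in% top$atoms$name)
  for (ch in chains) {
    region_maps[[ch]] <- aggregate_region_scores(
      cm, scheme, chain_a = ch, chain_b = ch,
      threshold = params$threshold, normalization = "per_pair_mean")
    profiles[[ch]] <- h12_profile(cm, scheme, chain = ch,
                                  threshold = params$threshold)
    ca_ch <- select_atoms(top, chain = ch, name = "CA")
    clusters[[ch]] <- daura_cluster(win, top,
                                    rmsd_cutoff = params$rmsd_cutoff,
                                    sel = ca_ch)
    if (has_backbone) {
      ha <- assign_helix(win, top, chains = ch)
      helicity[[ch]] <- segment_helicity(ha, ch,
                                         params$helix_segment[1],
                                         params$helix_segment[2])
    } else helicity[[ch]] <- NA_real_
    rmsf_tabs[[ch]] <- data.frame(
      chain = ch,
      resno = top$atoms$resno[ca_ch],
      rmsf = rmsf(aligned, sel = ca_ch),
      stringsAsFactors = FALSE)
  }
  verdict <- classify_activation(
    profiles, activation_threshold = params$activation_threshold,
    intermediate_lower = params$intermediate_lower)
  panel <- if (has_backbone && !is.na(isoform))
    signature_panel(top, win, isoform = isoform,
                    ligand = if (!is.null(sys$ligand)) sys$ligand else NA,
                    params = do.call(hbond_params, params$hbond))
  else NULL
  list(id = sys$id, status = "ok", isoform = isoform,
       ligand = if (!is.null(sys$ligand)) sys$ligand else NA,
       verdict = verdict, region_maps = region_maps, profiles = profiles,
       clusters = clusters, helicity = helicity, rmsf = rmsf_tabs,
       panel = panel,
       window = attr(win, "window"))
}

#' Run the full assay over a configured set of systems
#'
#' Per system: analysis window, joint Calpha superposition, DCCM, region
#' score maps, H12 profiles and activation verdict, per-monomer Daura
#' clustering, helical content of the mobile-helix segment, per-residue
#' RMSF, and the mechanistic signature panel. Failures of individual
#' systems are recorded and the run continues; schema violations in the
#' config abort before any work.
#'
#' @param config path to a YAML config file, or an equivalent list. Keys:
#'   `params` (optional overrides of thresholds/cutoffs/window),
#'   `systems` (list; each with `id` plus either `topology`, `trajectory`
#'   and `dt_ns`, or a `synthetic` spec block).
#' @param out_dir optional directory; when given, [write_report()] is
#'   called on the result.
#' @return Object of class `assay_report`.
#' @export
run_assay <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  params <- merge_params(config$params)
  scheme <- default_region_scheme()
  results <- list()
  for (sys in config$systems) {
    res <- tryCatch(analyse_system(sys, params, scheme),
                    error = function(e)
                      list(id = sys$id, status = "missing",
                           message = conditionMessage(e)))
    results[[sys$id]] <- res
  }
  report <- structure(list(params = params, results = results,
                           version = as.character(packageVersion("h12assay"))),
                      class = "assay_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.assay_report <- function(x, ...) {
  cat("<assay_report> ", length(x$results), " system(s)\n", sep = "")
  for (r in x$results) {
    if (r$status != "ok") {
      cat("  ", r$id, ": ", r$status, "\n", sep = "")
    } else {
      v <- r$verdict
      cat("  ", r$id, ": ",
          paste(sprintf("%s=%s(%.2f)", v$monomer, v$tier, v$score),
                collapse = " "),
          "; effective=", attr(v, "effective"), "\n", sep = "")
    }
  }
  invisible(x)
}

fmt_num <- function(x) formatC(x, digits = 10, format = "g")

#' Write an assay report as CSV tables plus a run log
#'
#' Emits `verdicts.csv`, `clusters.csv`, `helicity.csv`, `panel.csv`,
#' per-system H12-profile and region-map CSVs, per-system/monomer RMSF
#' CSVs and a human-readable `summary.txt` echoing every numeric
#' parameter. Output is deterministic: identical reports give
#' byte-identical files.
#'
#' @param report an `assay_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "assay_report"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create report directory '", dir, "'")
  verdicts <- list(); clusters <- list(); helicity <- list(); panels <- list()
  for (r in report$results) {
    if (r$status != "ok") {
      verdicts[[r$id]] <- data.frame(system_id = r$id, monomer = NA,
                                     score_h3 = NA, score_h5 = NA,
                                     score = NA, tier = NA,
                                     effective = NA, status = r$status,
                                     stringsAsFactors = FALSE)
      next
    }
    v <- r$verdict
    verdicts[[r$id]] <- data.frame(system_id = r$id, monomer = v$monomer,
                                   score_h3 = v$score_h3,
                                   score_h5 = v$score_h5, score = v$score,
                                   tier = v$tier,
                                   effective = attr(v, "effective"),
                                   status = "ok", stringsAsFactors = FALSE)
    for (ch in names(r$clusters)) {
      cl <- r$clusters[[ch]]
      clusters[[paste(r$id, ch)]] <- data.frame(
        system_id = r$id, monomer = ch,
        cluster = seq_along(cl$populations),
        population = cl$populations,
        center_frame = cl$window[cl$centers],
        stringsAsFactors = FALSE)
    }
    helicity[[r$id]] <- data.frame(
      system_id = r$id, monomer = names(r$helicity),
      helix_segment_content = unlist(r$helicity),
      stringsAsFactors = FALSE)
    if (!is.null(r$panel)) {
      p <- r$panel; p$system_id <- r$id
      panels[[r$id]] <- p[, c("system_id", setdiff(names(p), "system_id"))]
    }
    for (ch in names(r$profiles)) {
      utils::write.csv(r$profiles[[ch]]$per_residue,
                       file.path(dir, paste0("h12_profile_",
                                             make.names(r$id), "_", ch,
                                             ".csv")))
      utils::write.csv(r$region_maps[[ch]]$S,
                       file.path(dir, paste0("region_scores_",
                                             make.names(r$id), "_", ch,
                                             ".csv")))
      utils::write.csv(r$rmsf[[ch]],
                       file.path(dir, paste0("rmsf_", make.names(r$id),
                                             "_", ch, ".csv")),
                       row.names = FALSE)
    }
  }
  bind_or_empty <- function(lst, cols) {
    if (length(lst) > 0) do.call(rbind, unname(lst))
    else as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  write.csv(bind_or_empty(verdicts, c("system_id", "monomer", "score_h3",
                                      "score_h5", "score", "tier",
                                      "effective", "status")),
            file.path(dir, "verdicts.csv"), row.names = FALSE)
  write.csv(bind_or_empty(clusters, c("system_id", "monomer", "cluster",
                                      "population", "center_frame")),
            file.path(dir, "clusters.csv"), row.names = FALSE)
  write.csv(bind_or_empty(helicity, c("system_id", "monomer",
                                      "helix_segment_content")),
            file.path(dir, "helicity.csv"), row.names = FALSE)
  write.csv(bind_or_empty(panels, c("system_id", "isoform", "ligand",
                                    "monomer", "label", "kind",
                                    "persistence", "n_frames",
                                    "applicable")),
            file.path(dir, "panel.csv"), row.names = FALSE)
  p <- report$params
  log_lines <- c(
    paste0("h12assay version ", report$version),
    paste0("correlation threshold tau = ", fmt_num(p$threshold)),
    paste0("activation threshold = ", fmt_num(p$activation_threshold)),
    paste0("intermediate band lower edge = ", fmt_num(p$intermediate_lower)),
    paste0("cluster RMSD cutoff (A) = ", fmt_num(p$rmsd_cutoff)),
    paste0("hbond d_max (A) = ", fmt_num(p$hbond$d_max)),
    paste0("hbond theta_max (deg) = ", fmt_num(p$hbond$theta_max)),
    paste0("analysis window = ", p$window$mode, " ",
           fmt_num(p$window$value)),
    paste0("helix segment = ", p$helix_segment[1], "-", p$helix_segment[2]),
    "",
    vapply(report$results, function(r) {
      if (r$status != "ok") return(paste0(r$id, ": ", r$status))
      v <- r$verdict
      paste0(r$id, ": ",
             paste(sprintf("%s %s (score %.4f)", v$monomer, v$tier,
                           v$score), collapse = "; "),
             "; effective = ", attr(v, "effective"))
    }, character(1)))
  writeLines(log_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
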