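trajectory_required_cols <- function(species) {
  c("time_months", "season",
    as.vector(t(outer(c("N", "P", "G", "L", "R", "D"), species, paste,
                      sep = "_"))))
}

#' Write or read a trajectory as CSV
#'
#' One row per sample time, columns `time_months, season, N_<sp>..,
#' P_<sp>.., G_<sp>.., L_<sp>.., R_<sp>.., D_<sp>..`. Floating values are
#' written as full-precision decimal text (`%.17g`), so a write/read round
#' trip reproduces every value exactly and the files are diff-able.
#' `read_trajectory()` validates the schema and names the offending column
#' on failure.
#'
#' @param trajectory A `pest_trajectory`.
#' @param path File path.
#' @return `read_trajectory()` returns a `pest_trajectory` (without the
#'   generating scenario attribute); `write_trajectory()` returns `path`
#'   invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty trajectory file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("trajectory file has a header but no rows: ", path)
  n_cols <- grep("^N_", names(df), value = TRUE)
  if (!"time_months" %in% names(df))
    stop("trajectory schema violation: missing column time_months")
  if (length(n_cols) == 0)
    stop("trajectory schema violation: no N_<species> columns")
  species <- sub("^N_", "", n_cols)
  missing_cols <- setdiff(trajectory_required_cols(species), names(df))
  if (length(missing_cols) > 0)
    stop("trajectory schema violation: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  class(df) <- c("pest_trajectory", "data.frame")
  df
}

## canonical list of the 15 study systems: 4 sole, 6 pairs, 4 triples, 1 quad
all_study_systems <- function() {
  ids <- pest_species_ids()
  sets <- list()
  for (k in 1:4)
    sets <- c(sets, utils::combn(ids, k, simplify = FALSE))
  sets <- lapply(sets, canonical_species)
  names(sets) <- vapply(sets, paste, character(1), collapse = "+")
  sets
}

#' Run the full scenario gallery
#'
#' Simulates all 15 study systems (4 sole-species, 6 pairwise, 4
#' three-species, 1 four-species) plus the aggregated two-stock validation
#' run (the four-species system compiled into one host and one parasitoid
#' total), writing per-system trajectory CSVs, scenario snapshots, metric
#' CSVs, a combined dominance-share table and a run manifest. The whole
#' pipeline is deterministic: rerunning reproduces byte-identical files.
#'
#' @param output_dir Writable output directory (created if absent).
#' @param overrides Named list of scenario overrides applied to every
#'   system (see [pest_scenario()]).
#' @return Invisibly, the manifest: a data frame with one row per system
#'   (`system`, `n_species`, `trajectory`, `scenario`, `metrics` file
#'   paths, `wall_time_s`).
#' @export
#' @examples
#' \donttest{
#' manifest <- run_gallery(tempfile("gallery"))
#' }
run_gallery <- function(output_dir, overrides = list()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  systems <- all_study_systems()
  manifest <- list()
  shares_tab <- list()
  for (nm in names(systems)) {
    t0 <- proc.time()[["elapsed"]]
    id <- gsub("\\+", "_", nm)
    cfg <- pest_scenario(systems[[nm]], overrides = overrides)
    traj <- stats::simulate(cfg)
    traj_path <- file.path(output_dir, paste0(id, "_trajectory.csv"))
    cfg_path <- file.path(output_dir, paste0(id, "_scenario.json"))
    met_path <- file.path(output_dir, paste0(id, "_metrics.csv"))
    write_trajectory(traj, traj_path)
    write_scenario(cfg, cfg_path)
    pk <- peak_summary(traj)
    sh <- dominance_shares(traj)
    met <- data.frame(
      metric = c("mean_total_pests",
                 paste0("peak_", pk$table$stock),
                 paste0("peak_time_", pk$table$stock),
                 paste0("avg_share_", names(sh$averaged))),
      value = c(mean_total_pests(traj), pk$table$max, pk$table$t_max,
                sh$averaged),
      stringsAsFactors = FALSE
    )
    met$value <- sprintf("%.17g", met$value)
    utils::write.csv(met, met_path, row.names = FALSE, quote = FALSE)
    shares_tab[[nm]] <- data.frame(system = nm, species = names(sh$averaged),
                                   share_pct = 100 * sh$averaged,
                                   stringsAsFactors = FALSE)
    manifest[[nm]] <- data.frame(
      system = nm, n_species = length(systems[[nm]]),
      trajectory = traj_path, scenario = cfg_path, metrics = met_path,
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
      stringsAsFactors = FALSE
    )
  }
  ## aggregated two-stock validation run from the four-species system
  quad <- read_trajectory(manifest[["Sf+Bf+Sc+Cp"]]$trajectory)
  agg <- data.frame(time_months = quad$time_months, season = quad$season,
                    stringsAsFactors = FALSE)
  sp4 <- trajectory_species(quad)
  agg$N_all <- rowSums(as.matrix(quad[, paste0("N_", sp4)]))
  agg$P_all <- rowSums(as.matrix(quad[, paste0("P_", sp4)]))
  for (fl in c("G", "L", "R", "D"))
    agg[[paste0(fl, "_all")]] <- rowSums(as.matrix(quad[, paste0(fl, "_", sp4)]))
  class(agg) <- c("pest_trajectory", "data.frame")
  agg_path <- file.path(output_dir, "aggregated_trajectory.csv")
  write_trajectory(agg, agg_path)
  ph <- phase_diagram(agg)
  phase_path <- file.path(output_dir, "aggregated_phase.csv")
  ph_df <- ph$points
  for (nm2 in names(ph_df)) ph_df[[nm2]] <- sprintf("%.17g", ph_df[[nm2]])
  utils::write.csv(ph_df, phase_path, row.names = FALSE, quote = FALSE)
  manifest[["aggregated"]] <- data.frame(
    system = "aggregated", n_species = 1L, trajectory = agg_path,
    scenario = manifest[["Sf+Bf+Sc+Cp"]]$scenario, metrics = phase_path,
    wall_time_s = NA_real_, stringsAsFactors = FALSE
  )
  shares <- do.call(rbind, shares_tab)
  rownames(shares) <- NULL
  shares$share_pct <- sprintf("%.17g", shares$share_pct)
  utils::write.csv(shares, file.path(output_dir, "dominance_shares.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest[, names(manifest) != "wall_time_s"],
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
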