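#' Default run configuration
#'
#' All model defaults in one YAML-serializable list: input paths, rod
#' definitions, electrostatic and bending parameters, kinetics settings and
#' per-command options. Values mirror the package defaults (dielectric 80,
#' screening length 1.3 nm, lateral separation 2 nm, persistence length
#' 130 nm, bend grid radii 75-300 nm and arcs 15-40 nm, initial contact
#' 3.6 nm, 98-residue charge window).
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    output_dir = "minifil-out",
    fasta = NULL,
    rods = list(),        # per-id: rod_start, rod_end, phase, skips, register
    synthetic = list(n_sites = 1078L, repeat_sites = 196L, tip_sites = 25L,
                     tip_charge = 2, block_charge = -2, block_stride = 7L),
    electro = list(dielectric = 80, screening_length_nm = 1.3,
                   temperature_k = 298, lateral_sep_nm = 2,
                   cutoff_nm = 15.6),
    wlc = list(persistence_nm = 130, radius_range_nm = c(75, 300),
               arc_range_nm = c(15, 40), radius_steps = 16L,
               arc_steps = 11L, include_straight = TRUE),
    kinetics = list(x0_nm = 3.6, d_nm2 = 1, lo_step_sites = 7L,
                    grid_step_nm = 0.05),
    profile = list(window = 98L),
    scan = list(orientation = "parallel", s_min = 0, s_max = NULL,
                s_step = 0.1456),
    landscape = list(orientation = "parallel", s_min = 0, s_max = NULL,
                     s_step = 1.456),
    contact = list(orientation = "parallel", s_min = 5, s_max = NULL,
                   s_step = 1.456),
    field = list(r_nm = 2, z_min = -10, z_max = 170, z_step = 1),
    seed = NULL
  ), class = "run_config")
}

merge_config <- function(base, extra) {
  for (k in names(extra)) {
    if (is.list(base[[k]]) && is.list(extra[[k]]) &&
        !is.null(names(extra[[k]])))
      base[k] <- list(merge_config(base[[k]], extra[[k]]))
    else base[k] <- list(extra[[k]]) # keeps explicit NULLs
  }
  base
}

#' Read / write a run configuration
#'
#' YAML round-trip of a [default_run_config()]-shaped document; values
#' absent from the file keep their defaults.
#'
#' @param path YAML file.
#' @return `read_run_config()` returns a `run_config` list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path) %||% list()
  cfg <- merge_config(unclass(default_run_config()), user)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_params <- function(config) {
  e <- config$electro
  list(
    electro = electro_params(e$dielectric, e$screening_length_nm,
                             e$temperature_k, e$lateral_sep_nm, e$cutoff_nm),
    wlc = do.call(wlc_params, config$wlc)
  )
}

load_config_chains <- function(config) {
  if (is.null(config$fasta)) {
    syn <- do.call(synthetic_rod, c(config$synthetic,
                                    list(seed = config$seed)))
    return(stats::setNames(list(syn), attr(syn, "label")))
  }
  recs <- read_rod_fasta(config$fasta)
  chains <- lapply(seq_len(nrow(recs)), function(i) {
    rec <- recs[i, ]
    rc <- config$rods[[rec$id]] %||% list()
    rec <- rod_record(rec$id, rec$sequence,
                      rc$rod_start %||% rec$rod_start,
                      rc$rod_end %||% rec$rod_end,
                      rc$skips %||% integer(0))
    reg <- if (!is.null(rc$register))
      assign_register(rec, "file", rc$register)
    else assign_register(rec, "fallback", phase = rc$phase %||% "a")
    build_charge_chain(rec, reg)
  })
  stats::setNames(chains, recs$id)
}

provenance_header <- function(config, extra = character()) {
  flat <- unlist(unclass(config), use.names = TRUE)
  c(extra, stats::setNames(as.character(flat), names(flat)))
}

#' Run one pipeline command
#'
#' Thin driver tying the modules together for shell use: loads the chains
#' named by the configuration (or the synthetic rod when no FASTA is
#' given), runs one command and writes TSV output files whose `#` headers
#' record the full parameter set, so identical configurations reproduce
#' byte-identical files.
#'
#' Commands: `chain` (charge chains), `profile` (windowed charge
#' profiles), `scan` (straight-rod stagger scan), `landscape`
#' (stagger/overlap energy landscape), `contact-time` (contact-time
#' profile), `matrix` (ordered-pair contact-time summary),
#' `potential-field` (potential around each rod), `fixtures` (synthetic
#' rod TSV + FASTA/register files).
#'
#' @param config A `run_config` list or the path to a YAML config.
#' @param command One of the commands above.
#' @return Character vector of the files written, invisibly.
#' @export
run_pipeline <- function(config,
                         command = c("chain", "profile", "scan", "landscape",
                                     "contact-time", "matrix",
                                     "potential-field", "fixtures")) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config_params(config)
  hdr <- provenance_header(config, c(command = command))
  out <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$output_dir, name)
    write_tsv_with_header(as.data.frame(df), path, hdr)
    out <<- c(out, path)
  }

  if (command == "fixtures") {
    syn <- do.call(synthetic_rod, c(config$synthetic,
                                    list(seed = config$seed)))
    emit(data.frame(site_index = syn$site,
                    axial_position_nm = syn$position_nm,
                    charge_e = syn$charge), "synthetic_rod.tsv")
    fa <- file.path(config$output_dir, "synthetic_rod.fasta")
    rg <- file.path(config$output_dir, "synthetic_rod.register.tsv")
    synthetic_rod_fasta(syn, fa, rg)
    out <- c(out, fa, rg)
    return(invisible(out))
  }

  chains <- load_config_chains(config)
  first2 <- function() {
    if (length(chains) == 1) list(a = chains[[1]], b = chains[[1]])
    else list(a = chains[[1]], b = chains[[2]])
  }

  if (command == "chain") {
    for (id in names(chains))
      emit(data.frame(site_index = chains[[id]]$site,
                      axial_position_nm = chains[[id]]$position_nm,
                      charge_e = chains[[id]]$charge),
           paste0(gsub("[^A-Za-z0-9._-]", "_", id), ".chain.tsv"))
  } else if (command == "profile") {
    for (id in names(chains))
      emit(charge_profile(chains[[id]], config$profile$window),
           paste0(gsub("[^A-Za-z0-9._-]", "_", id), ".profile.tsv"))
  } else if (command == "scan") {
    ch <- first2()
    sc <- config$scan
    emit(stagger_scan(ch$a, ch$b, sc$orientation, sc$s_min,
                      sc$s_max %||% rod_length(ch$a), sc$s_step, p$electro),
         "stagger_scan.tsv")
  } else if (command == "landscape") {
    ch <- first2()
    sc <- config$landscape
    ss <- seq(sc$s_min, sc$s_max %||% (rod_length(ch$a) - 5), by = sc$s_step)
    emit(energy_landscape(ch$a, ch$b, sc$orientation, ss,
                          config$kinetics$lo_step_sites, p$electro, p$wlc),
         "energy_landscape.tsv")
  } else if (command == "contact-time") {
    ch <- first2()
    sc <- config$contact
    k <- config$kinetics
    ss <- seq(sc$s_min, sc$s_max %||% (rod_length(ch$a) - k$x0_nm),
              by = sc$s_step)
    emit(contact_time_profile(ch$a, ch$b, sc$orientation, ss,
                              k$lo_step_sites, p$electro, p$wlc,
                              k$x0_nm, k$d_nm2, k$grid_step_nm),
         "contact_time_profile.tsv")
  } else if (command == "matrix") {
    sc <- config$contact
    k <- config$kinetics
    ss <- seq(sc$s_min,
              sc$s_max %||% (min(vapply(chains, rod_length, numeric(1))) -
                               k$x0_nm),
              by = sc$s_step)
    m <- contact_time_matrix(chains, sc$orientation, ss, k$lo_step_sites,
                             p$electro, p$wlc, k$x0_nm, k$d_nm2,
                             k$grid_step_nm)
    emit(m[c("straight", "bent", "orientation", "peak_stagger_nm",
             "peak_dt1_nm2", "mean_dt1_nm2")], "contact_time_matrix.tsv")
  } else if (command == "potential-field") {
    f <- config$field
    for (id in names(chains))
      emit(potential_field(chains[[id]], f$r_nm,
                           seq(f$z_min, f$z_max, by = f$z_step), p$electro),
           paste0(gsub("[^A-Za-z0-9._-]", "_", id), ".field.tsv"))
  }
  invisible(out)
}
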