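#' Read heavy-chain sequences from a FASTA file
#'
#' One row per FASTA entry, in file order. Sequences are normalized to upper
#' case. The rod interval defaults to the full sequence until overridden
#' (see [rod_record()]); skip positions start empty.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `id`, `sequence`, `rod_start`, `rod_end`
#'   and a list-column `skip_positions`.
#' @export
read_rod_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readAAStringSet(path),
      error = function(e) abort(paste0("malformed FASTA '", path, "': ",
                                       conditionMessage(e)))),
    warning = function(w) abort(paste0("malformed FASTA '", path, "': ",
                                       conditionMessage(w)))
  )
  if (length(set) == 0) abort(paste0("FASTA file '", path, "' is empty"))
  seqs <- unname(toupper(as.character(set)))
  first_line <- vapply(seqs, function(s) {
    bad <- regmatches(s, regexpr("[^ACDEFGHIKLMNPQRSTVWY]", s))
    if (length(bad)) bad else ""
  }, character(1))
  if (any(nzchar(first_line)))
    abort(paste0("non-standard residue code '",
                 first_line[nzchar(first_line)][1], "' in FASTA '", path, "'"))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  tibble(id = ids, sequence = unname(seqs),
         rod_start = 1L, rod_end = nchar(seqs),
         skip_positions = rep(list(integer(0)), length(seqs)))
}

#' Describe one heavy-chain rod
#'
#' Builds (or rebuilds) a single-record tibble with validated rod
#' boundaries and skip residues. Residue coordinates are 1-based and
#' inclusive, as in the register annotation files.
#'
#' @param id Accession or free-text label.
#' @param sequence One-letter amino-acid string (upper or lower case).
#' @param rod_start,rod_end 1-based inclusive residue indices delimiting the
#'   coiled-coil rod that is modelled; default to the whole sequence.
#' @param skip_positions Integer vector of 1-based residue indices of skip
#'   residues, all within `[rod_start, rod_end]`.
#' @return A one-row tibble like [read_rod_fasta()] returns.
#' @export
rod_record <- function(id, sequence, rod_start = 1L,
                       rod_end = nchar(sequence),
                       skip_positions = integer(0)) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)) {
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", sequence)
    abort(sprintf("non-standard residue '%s' at position %d in '%s'",
                  substr(sequence, bad, bad), bad, id))
  }
  rod_start <- as.integer(rod_start); rod_end <- as.integer(rod_end)
  if (!(rod_start >= 1 && rod_start <= rod_end && rod_end <= n))
    abort(sprintf("need 1 <= rod_start <= rod_end <= %d for '%s'", n, id))
  skip_positions <- sort(unique(as.integer(skip_positions)))
  if (length(skip_positions) &&
      (min(skip_positions) < rod_start || max(skip_positions) > rod_end))
    abort("skip_positions must lie within [rod_start, rod_end]")
  tibble(id = id, sequence = sequence, rod_start = rod_start,
         rod_end = rod_end, skip_positions = list(skip_positions))
}

.register_labels <- c(letters[1:7], "skip", "none")

#' Assign the heptad register of a rod
#'
#' The register says where each rod residue sits in the a-g heptad repeat of
#' the coiled-coil; positions `a` and `d` face the hydrophobic core and have
#' their charges cancelled downstream. The register is taken as an input:
#' either read from an annotation file (`mode = "file"`, TSV with columns
#' `residue_index` and `label`, aligned to the rod interval) or produced by
#' a fallback that cycles `a..g` from a configured start phase, labels the
#' record's skip positions as `"skip"`, and resumes the cycle after each
#' skip without advancing the phase.
#'
#' @param record A one-row record from [rod_record()] / [read_rod_fasta()].
#' @param mode `"fallback"` (default) or `"file"`.
#' @param register_path Annotation file, required for `mode = "file"`.
#' @param phase Heptad letter of the first rod residue for the fallback.
#' @return A tibble with columns `residue_index`, `residue`, `label`
#'   covering `rod_start:rod_end`.
#' @examples
#' r <- rod_record("toy", "MKELQDRLAK", rod_start = 2, rod_end = 9)
#' assign_register(r, phase = "a")
#' @export
assign_register <- function(record, mode = c("fallback", "file"),
                            register_path = NULL, phase = "a") {
  mode <- match.arg(mode)
  stopifnot(nrow(record) == 1)
  idx <- record$rod_start:record$rod_end
  res <- strsplit(substr(record$sequence, record$rod_start, record$rod_end),
                  "")[[1]]
  if (mode == "file") {
    if (is.null(register_path)) abort("mode = 'file' needs register_path")
    reg <- utils::read.delim(register_path, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (!all(c("residue_index", "label") %in% names(reg)))
      abort("register file needs columns residue_index and label")
    if (nrow(reg) != length(idx))
      abort(sprintf("register has %d rows but the rod interval has %d residues",
                    nrow(reg), length(idx)))
    if (!all(reg$residue_index == idx))
      abort("register residue_index does not match the rod interval")
    lab <- tolower(reg$label)
    if (!all(lab %in% .register_labels))
      abort(paste0("invalid register label(s): ",
                   paste(unique(setdiff(lab, .register_labels)), collapse = ", ")))
    return(tibble(residue_index = idx, residue = res, label = lab))
  }
  phase <- tolower(phase)
  if (!phase %in% letters[1:7]) abort("phase must be one of a..g")
  skips <- record$skip_positions[[1]]
  lab <- character(length(idx))
  is_skip <- idx %in% skips
  lab[is_skip] <- "skip"
  k <- sum(!is_skip)
  lab[!is_skip] <- letters[1:7][((match(phase, letters) - 1) + seq_len(k) - 1) %% 7 + 1]
  tibble(residue_index = idx, residue = res, label = lab)
}

.residue_charge <- c(R = 2, K = 2, D = -2, E = -2)

new_charge_chain <- function(charge, label, spacing = rod_spacing_nm,
                             extra = NULL) {
  n <- length(charge)
  out <- tibble(site = seq_len(n) - 1L,
                position_nm = (seq_len(n) - 1L) * spacing,
                charge = as.numeric(charge))
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  structure(out, label = label, spacing = spacing,
            class = c("charge_chain", class(out)))
}

validate_charge_chain <- function(chain) {
  if (!all(c("site", "position_nm", "charge") %in% names(chain)))
    abort("not a charge chain: need columns site, position_nm, charge")
  if (!all(chain$charge %in% c(-2, 0, 2)))
    abort("charge chain charges must be in {-2, 0, +2} e")
  spacing <- attr(chain, "spacing") %||% rod_spacing_nm
  d <- diff(chain$position_nm)
  if (nrow(chain) > 1 && (any(d <= 0) || max(abs(d - spacing)) > 1e-9))
    abort("axial positions must increase with constant spacing")
  chain
}

#' Length of a rod in nm
#'
#' Distance between the first and last charge site,
#' `(n_sites - 1) * spacing`.
#' @param chain A charge chain.
#' @return Length in nm.
#' @export
rod_length <- function(chain) {
  (nrow(chain) - 1) * (attr(chain, "spacing") %||% rod_spacing_nm)
}

#' Build the linear charge chain of a rod
#'
#' Converts the rod interval of a heavy-chain record into an ordered chain
#' of point charges on the 0.1456 nm coiled-coil lattice. Each rod residue
#' (skip residues included) becomes one site; arginine and lysine carry
#' +2 e and aspartate and glutamate -2 e (the factor 2 because the rod is a
#' dimer of two identical heavy chains); residues at heptad positions `a`
#' or `d` are buried in the hydrophobic seam and their charges are
#' cancelled; everything else is 0.
#'
#' @param record A one-row record from [rod_record()].
#' @param register A register tibble from [assign_register()], aligned to
#'   the rod interval.
#' @return A `charge_chain` tibble with columns `site` (0-based),
#'   `position_nm`, `charge`, `residue_index`, `residue`, `register`.
#' @examples
#' r <- rod_record("toy", "KAEKAEK")
#' build_charge_chain(r, assign_register(r, phase = "a"))
#' @export
build_charge_chain <- function(record, register) {
  stopifnot(nrow(record) == 1)
  idx <- record$rod_start:record$rod_end
  if (nrow(register) != length(idx) || !all(register$residue_index == idx))
    abort("register is not aligned to the record's rod interval")
  res <- register$residue
  bad <- which(!res %in% c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  if (length(bad))
    abort(paste0("unknown residue code at rod position(s) ",
                 paste(idx[bad], collapse = ", ")))
  q <- unname(.residue_charge[res])
  q[is.na(q)] <- 0
  q[register$label %in% c("a", "d")] <- 0
  new_charge_chain(q, label = record$id,
                   extra = tibble(residue_index = idx, residue = res,
                                  register = register$label))
}

#' Sliding-window charge profile along a rod
#'
#' Sums the site charges over a sliding window (default 98 residues, half
#' the 196-residue charge repeat) to show the coarse charge pattern of the
#' rod: for NM2 rods, a positive C-terminal tip and five regions of
#' increased net negativity.
#'
#' @param chain A charge chain.
#' @param window Window size in residues (default 98).
#' @return A `charge_profile` tibble with columns `center_nm` (window
#'   midpoint) and `net_charge_e` (exact windowed sum).
#' @export
charge_profile <- function(chain, window = 98) {
  chain <- validate_charge_chain(chain)
  n <- nrow(chain)
  window <- as.integer(window)
  if (window < 1 || window > n)
    abort(sprintf("window (%d) must be between 1 and n_sites (%d)", window, n))
  cs <- cumsum(c(0, chain$charge))
  sums <- cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]
  centers <- (chain$position_nm[1:(n - window + 1)] +
                chain$position_nm[window:n]) / 2
  structure(tibble(center_nm = centers, net_charge_e = sums),
            window = window, label = attr(chain, "label"),
            class = c("charge_profile", class(tibble())))
}

#' @export
print.charge_chain <- function(x, ...) {
  cat(sprintf("# charge chain '%s': %d sites, %.1f nm, net %+g e\n",
              attr(x, "label") %||% "?", nrow(x), rod_length(x),
              sum(x$charge)))
  NextMethod()
}

#' Export a charge chain as TSV
#'
#' Writes columns `site_index`, `axial_position_nm`, `charge_e` with a
#' `#`-prefixed provenance header.
#'
#' @param chain A charge chain.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_charge_chain <- function(chain, path) {
  chain <- validate_charge_chain(chain)
  out <- data.frame(site_index = chain$site,
                    axial_position_nm = chain$position_nm,
                    charge_e = chain$charge)
  write_tsv_with_header(out, path, c(
    label = attr(chain, "label") %||% "",
    spacing_nm = attr(chain, "spacing") %||% rod_spacing_nm,
    n_sites = nrow(chain), net_charge_e = sum(chain$charge)))
}

#' Read a charge chain written by [write_charge_chain()]
#' @param path TSV file.
#' @param label Optional label override.
#' @return A `charge_chain` tibble.
#' @export
read_charge_chain <- function(path, label = NULL) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("site_index", "axial_position_nm", "charge_e") %in% names(d)))
    abort("not a charge-chain TSV")
  hdr <- read_tsv_header(path)
  new_charge_chain(d$charge_e,
                   label = label %||% hdr[["label"]] %||% basename(path),
                   spacing = as.numeric(hdr[["spacing_nm"]] %||% rod_spacing_nm))
}

#' Load a charge chain from a FASTA / register file pair
#'
#' Convenience wrapper: reads the first record of a FASTA file, restricts it
#' to the given rod interval, assigns the register (from a file when given,
#' otherwise the fallback cycle) and builds the charge chain.
#'
#' @param fasta_path FASTA file (first record used).
#' @param register_path Optional register annotation TSV.
#' @inheritParams rod_record
#' @inheritParams assign_register
#' @return A `charge_chain`.
#' @export
load_rod_chain <- function(fasta_path, register_path = NULL,
                           rod_start = NULL, rod_end = NULL,
                           skip_positions = integer(0), phase = "a") {
  rec <- read_rod_fasta(fasta_path)[1, ]
  rec <- rod_record(rec$id, rec$sequence,
                    rod_start %||% rec$rod_start,
                    rod_end %||% rec$rod_end, skip_positions)
  reg <- if (!is.null(register_path))
    assign_register(rec, "file", register_path)
  else assign_register(rec, "fallback", phase = phase)
  build_charge_chain(rec, reg)
}

write_tsv_with_header <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(sprintf("# %s: %s", names(header), unname(header)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_header <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[startsWith(lines, "# ")]
  kv <- regmatches(lines, regexec("^# ([^:]+): (.*)$", lines))
  out <- lapply(kv, function(m) if (length(m) == 3) m[3] else NULL)
  names(out) <- vapply(kv, function(m) if (length(m) == 3) m[2] else "",
                       character(1))
  out[nzchar(names(out))]
}
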