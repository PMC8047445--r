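#' Read a FASTA proteome
#'
#' Standard FASTA; the protein id is the description line up to the first
#' whitespace, sequences are uppercased. Duplicate ids are an error.
#'
#' @param path FASTA file.
#' @return A [proteome_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0) stop("empty FASTA: ", path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1)
  proteome_set(setNames(as.character(aas), ids),
               provenance = paste("read from", basename(path)))
}

#' Write a proteome as FASTA
#' @param proteome a [proteome_set()].
#' @param path output file.
#' @export
write_fasta <- function(proteome, path) {
  aas <- Biostrings::AAStringSet(proteome$records)
  Biostrings::writeXStringSet(aas, path, width = 60)
  invisible(path)
}

# shared delimited reader: header required, '#' comments allowed
read_delim_table <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(
    read.table(path, header = TRUE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (nrow(tab) == 0) stop("empty input: ", path)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Read a titration peak table
#'
#' Whitespace/tab-delimited text with header columns `residue h_ppm n_ppm
#' intensity ligand_uM protein_uM`; `#` comments allowed.
#'
#' @param path input file.
#' @return A [titration_series()].
#' @export
read_peak_table <- function(path) {
  tab <- read_delim_table(path, c("residue", "h_ppm", "n_ppm", "intensity",
                                  "ligand_uM", "protein_uM"))
  titration_series(tab)
}

#' Write a titration peak table
#' @param series a [titration_series()].
#' @param path output file.
#' @export
write_peak_table <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# titration peak table: one row per (residue, ligand point)", con)
  write.table(as.data.frame(series), con, row.names = FALSE, quote = FALSE,
              sep = "\t")
  invisible(path)
}

#' Read a dispersion table
#'
#' Columns `residue field_mhz nu_cpmg` plus either `r2eff` (and optionally
#' `sigma`) or `intensity` with `i0`; the relaxation delay is taken from a
#' `# t_cpmg_s = <value>` comment line (or the `t_cpmg` argument).
#'
#' @param path input file.
#' @param t_cpmg relaxation delay (s); overrides any header directive.
#' @return A [dispersion_dataset()].
#' @export
read_dispersion_table <- function(path, t_cpmg = NULL) {
  if (is.null(t_cpmg)) {
    hdr <- grep("t_cpmg_s", readLines(path, n = 20), value = TRUE)
    if (length(hdr))
      t_cpmg <- as.numeric(sub(".*t_cpmg_s\\s*=\\s*([0-9.eE+-]+).*", "\\1",
                               hdr[1]))
  }
  if (is.null(t_cpmg) || !is.finite(t_cpmg))
    stop("no t_cpmg: supply the argument or a '# t_cpmg_s = ...' header line")
  tab <- read_delim_table(path, c("residue", "field_mhz", "nu_cpmg"))
  if (!"r2eff" %in% names(tab)) {
    if (!all(c("intensity", "i0") %in% names(tab)))
      stop(path, ": need either r2eff or intensity + i0 columns")
    tab$r2eff <- r2eff_from_intensity(tab$intensity, tab$i0, t_cpmg)
  }
  dispersion_dataset(tab[c("residue", "field_mhz", "nu_cpmg", "r2eff",
                           intersect("sigma", names(tab)))], t_cpmg = t_cpmg)
}

#' Write a dispersion table
#' @param dataset a [dispersion_dataset()].
#' @param path output file.
#' @export
write_dispersion_table <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_cpmg_s = %g", attr(dataset, "t_cpmg")), con)
  write.table(as.data.frame(dataset), con, row.names = FALSE, quote = FALSE,
              sep = "\t")
  invisible(path)
}

#' Read a disorder mask
#'
#' 3-column delimited text `protein_id start end`, 0-based half-open
#' coordinates (stated in the file header); `#` comments allowed.
#'
#' @param path input file.
#' @param proteome optional [proteome_set()] for bounds checking.
#' @return A [disorder_mask()].
#' @export
read_mask <- function(path, proteome = NULL) {
  tab <- read_delim_table(path, c("protein_id", "start", "end"))
  ivs <- lapply(split(tab, tab$protein_id), function(d)
    as.matrix(d[order(d$start), c("start", "end")]))
  disorder_mask(ivs, proteome)
}

#' Write a disorder mask
#' @param mask a [disorder_mask()].
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# disorder intervals, 0-based half-open [start, end)", con)
  rows <- do.call(rbind, lapply(names(mask), function(id)
    data.frame(protein_id = id, start = mask[[id]][, 1], end = mask[[id]][, 2])))
  write.table(rows, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Read a peptide trajectory
#'
#' Plain-text model-per-frame dialect written by [write_trajectory()]:
#' `# unit:` and `# dt_ps:` directives, an `ATOM res_id res_name atom_name`
#' table, then `MODEL k` blocks with one `x y z` line per atom.
#'
#' @param path input file.
#' @return A [peptide_trajectory()].
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  if (!length(ln)) stop("empty input: ", path)
  unit <- sub("# unit:\\s*", "", grep("^# unit:", ln, value = TRUE)[1])
  dt <- as.numeric(sub("# dt_ps:\\s*", "", grep("^# dt_ps:", ln, value = TRUE)[1]))
  atom_ln <- grep("^ATOM\\b", ln, value = TRUE)
  if (!length(atom_ln)) stop(path, ": no ATOM table")
  at <- do.call(rbind, lapply(strsplit(atom_ln, "\\s+"), function(x)
    data.frame(res_id = as.integer(x[2]), res_name = x[3], atom_name = x[4])))
  n_atoms <- nrow(at)
  starts <- grep("^MODEL\\b", ln)
  if (!length(starts)) stop(path, ": no MODEL frames")
  coords <- array(NA_real_, c(n_atoms, 3, length(starts)))
  for (k in seq_along(starts)) {
    block <- ln[(starts[k] + 1):(starts[k] + n_atoms)]
    xyz <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
    if (ncol(xyz) != 3 || anyNA(xyz))
      stop(path, ": malformed frame ", k)
    coords[, , k] <- xyz
  }
  peptide_trajectory(coords, at, dt_ps = ifelse(is.finite(dt), dt, 1),
                     unit = ifelse(is.na(unit), "angstrom", unit))
}

#' Write a peptide trajectory
#' @param traj a [peptide_trajectory()].
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# unit: angstrom", sprintf("# dt_ps: %g", traj$dt_ps)), con)
  writeLines(sprintf("ATOM %d %s %s", traj$atoms$res_id, traj$atoms$res_name,
                     traj$atoms$atom_name), con)
  for (k in seq_len(dim(traj$coords)[3])) {
    writeLines(sprintf("MODEL %d", k), con)
    writeLines(apply(traj$coords[, , k], 1, function(v)
      sprintf("%.6f %.6f %.6f", v[1], v[2], v[3])), con)
  }
  invisible(path)
}

#' Run an end-to-end analysis
#'
#' Orchestrates either the binding pipeline (titration fit, expected bound
#' fraction at the CPMG sample conditions, constrained CPMG fit, rate
#' constants) or the census pipeline (motif counts, chi-squared, enrichment).
#'
#' @param config list. For `kind = "binding"`: `series`
#'   ([titration_series()]), `dispersion` ([dispersion_dataset()]),
#'   `ligand_uM`, `protein_uM` (CPMG sample totals), optional `residues`.
#'   For `kind = "census"`: `proteome`, `mask`, optional `families`.
#' @return A report list with every fitted parameter and the echoed config.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$kind) || !config$kind %in% c("binding", "census"))
    stop("config$kind must be 'binding' or 'census'")
  if (config$kind == "binding") {
    for (f in c("series", "dispersion", "ligand_uM", "protein_uM"))
      if (is.null(config[[f]])) stop("binding config needs '", f, "'")
    residues <- config$residues
    if (is.null(residues)) residues <- select_fast_exchange(config$series)
    if (!length(residues)) stop("stage select_fast_exchange: no residues")
    fit <- fit_global_kd(config$series, residues)
    pb_calc <- expected_bound_fraction(fit$kd, config$ligand_uM,
                                       config$protein_uM)
    cfit <- fit_dispersion_global(config$dispersion, mode = "constrained",
                                  fixed_p_b = pb_calc)
    rates <- rates_from_exchange(cfit$p_b, cfit$k_ex,
                                 config$ligand_uM, config$protein_uM,
                                 cov_pk = cfit$cov_pk)
    list(kind = "binding", kd_titration = fit$kd, kd_titration_sd = fit$kd_sd,
         pb_calc = pb_calc, k_ex = cfit$k_ex, k_off = rates$k_off,
         k_on = rates$k_on, kd_cpmg = rates$kd,
         reduced_chi2 = cfit$reduced_chi2, fit = fit, cpmg_fit = cfit,
         config = config[setdiff(names(config), c("series", "dispersion"))])
  } else {
    for (f in c("proteome", "mask"))
      if (is.null(config[[f]])) stop("census config needs '", f, "'")
    families <- config$families
    if (is.null(families)) families <- ixiv_families()
    cen <- census(config$proteome, config$mask, families)
    chi_d <- chi_square_total(cen$observed[, , "disordered"],
                              cen$expected[, , "disordered"])
    chi_s <- chi_square_total(cen$observed[, , "structured"],
                              cen$expected[, , "structured"])
    list(kind = "census", census = cen,
         chi2_disordered = chi_d, chi2_structured = chi_s,
         enrichment = enrichment_profile(cen),
         config = config[setdiff(names(config), c("proteome", "mask"))])
  }
}
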