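#' Proteome container
#'
#' @param records named character vector of uppercase amino-acid sequences;
#'   names are protein ids.
#' @param provenance free-text note on sequence origin.
#' @return A `proteome_set`.
#' @export
proteome_set <- function(records, provenance = "") {
  if (is.null(names(records)) || any(names(records) == ""))
    stop("every sequence needs a protein id")
  if (anyDuplicated(names(records)))
    stop("duplicate protein ids: ",
         paste(unique(names(records)[duplicated(names(records))]), collapse = ", "))
  records <- setNames(toupper(as.character(records)), names(records))
  if (any(nchar(records) == 0)) stop("empty sequence(s)")
  structure(list(records = records, provenance = provenance),
            class = "proteome_set")
}

#' Disorder mask
#'
#' Per-protein intervals of predicted intrinsic disorder, 0-based half-open,
#' sorted, non-overlapping, each at least 20 residues long.
#'
#' @param intervals named list; each element a 2-column matrix (start, end).
#' @param proteome optional [proteome_set()] to check bounds against.
#' @export
disorder_mask <- function(intervals, proteome = NULL) {
  for (id in names(intervals)) {
    iv <- intervals[[id]]
    if (is.null(dim(iv))) iv <- matrix(iv, ncol = 2)
    storage.mode(iv) <- "integer"
    if (any(iv[, 2] <= iv[, 1])) stop("empty/negative interval for ", id)
    if (any(iv[, 2] - iv[, 1] < 20))
      stop("interval shorter than 20 residues for ", id)
    if (nrow(iv) > 1) {
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
        stop("overlapping intervals for ", id)
    }
    if (any(iv[, 1] < 0)) stop("negative start for ", id)
    if (!is.null(proteome)) {
      if (!id %in% names(proteome$records))
        stop("mask refers to unknown protein ", id)
      if (any(iv[, 2] > nchar(proteome$records[[id]])))
        stop("interval out of bounds for ", id)
    }
    intervals[[id]] <- iv
  }
  structure(intervals, class = "disorder_mask")
}

#' Positional motif query
#'
#' An ordered list of allowed-residue sets, one per motif position; `"x"`
#' (or `"."`) denotes any of the 20 standard amino acids. `slim_query("[VI]x[VI]")`
#' or `slim_query("IxV")` build the IxI/V-family tripeptide queries.
#'
#' @param pattern string such as `"[VI]x[VI]"`, `"IPV"`, `"VxV"`.
#' @return A `motif_query`: list of character vectors.
#' @export
slim_query <- function(pattern) {
  toks <- regmatches(pattern, gregexpr("\\[[A-Za-z]+\\]|[A-Za-z.]", pattern))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != pattern)
    stop("cannot parse motif pattern: ", pattern)
  pos <- lapply(toks, function(t) {
    if (t %in% c("x", "X", ".")) return(.AA20)
    t <- gsub("\\[|\\]", "", t)
    aa <- toupper(strsplit(t, "")[[1]])
    bad <- setdiff(aa, .AA20)
    if (length(bad)) stop("non-standard residues in query: ",
                          paste(bad, collapse = ","))
    aa
  })
  structure(pos, class = "motif_query")
}

#' The four IxI/V motif families
#'
#' `IxI`, `IxV`, `VxI`, `VxV`: fixed flanks, free central residue.
#' @return Named list of [slim_query()] objects.
#' @export
ixiv_families <- function() {
  list(IxI = slim_query("IxI"), IxV = slim_query("IxV"),
       VxI = slim_query("VxI"), VxV = slim_query("VxV"))
}

#' Scan a sequence for motif matches
#'
#' Every (possibly overlapping) window whose residues all satisfy the
#' positional sets; windows containing non-standard letters never match.
#'
#' @param sequence amino-acid string.
#' @param query a [slim_query()].
#' @return Integer vector of 0-based window start positions.
#' @export
scan_motifs <- function(sequence, query) {
  v <- strsplit(toupper(sequence), "")[[1]]
  n <- length(query)
  L <- length(v)
  if (L < n) return(integer(0))
  ok <- rep(TRUE, L - n + 1)
  for (q in seq_len(n)) {
    ok <- ok & (v[q:(L - n + q)] %in% query[[q]])
  }
  which(ok) - 1L
}

#' Expected motif count from amino-acid frequencies
#'
#' `N = M * prod_q p(position q)` under positional independence; the
#' probability of a set-valued position is the sum of its members'
#' frequencies.
#'
#' @param query a [slim_query()].
#' @param frequencies named per-residue frequency vector of the database.
#' @param total_windows number of length-n windows in the database.
#' @export
expected_count <- function(query, frequencies, total_windows) {
  stopifnot(all(frequencies >= 0), total_windows >= 0)
  p <- vapply(query, function(aa)
    sum(frequencies[aa], na.rm = TRUE), numeric(1))
  total_windows * prod(p)
}

# per-protein disorder membership as a logical vector
disorder_vector <- function(len, iv) {
  d <- rep(FALSE, len)
  if (!is.null(iv)) for (k in seq_len(nrow(iv))) d[(iv[k, 1] + 1):iv[k, 2]] <- TRUE
  d
}

#' Proteome-wide motif census
#'
#' Counts matches of each motif family, stratified by the central residue,
#' in three databases: the whole proteome, its disordered regions (windows
#' entirely inside one disorder interval), and -- by subtraction -- its
#' structured remainder. Also tallies window totals and amino-acid
#' frequencies per database (standard residues only) and the expected counts
#' under the independence null.
#'
#' @param proteome a [proteome_set()].
#' @param mask a [disorder_mask()] (may cover a subset of proteins).
#' @param families named list of 3-position [slim_query()] objects with a
#'   fixed first/last position and a free (ANY) centre; default
#'   [ixiv_families()].
#' @return A `census_result`: `observed` and `expected` (3D arrays family x
#'   central-residue x database), `window_totals`, `frequencies` (20 x 3).
#' @export
census <- function(proteome, mask = disorder_mask(list()),
                   families = ixiv_families()) {
  stopifnot(inherits(proteome, "proteome_set"))
  if (!inherits(mask, "disorder_mask")) mask <- disorder_mask(mask, proteome)
  unknown <- setdiff(names(mask), names(proteome$records))
  if (length(unknown)) stop("mask refers to unknown protein ", unknown[1])
  fam_names <- names(families)
  n <- 3L
  dbs <- c("proteome", "disordered", "structured")
  obs <- array(0, dim = c(length(families), 20, 3),
               dimnames = list(fam_names, .AA20, dbs))
  res_counts <- matrix(0, 20, 2, dimnames = list(.AA20, c("proteome", "disordered")))
  win_tot <- c(proteome = 0, disordered = 0, structured = 0)

  for (id in names(proteome$records)) {
    v <- strsplit(proteome$records[[id]], "")[[1]]
    L <- length(v)
    iv <- if (id %in% names(mask)) mask[[id]] else NULL
    if (!is.null(iv) && any(iv[, 2] > L))
      stop("interval out of bounds for ", id)
    dis <- disorder_vector(L, iv)
    std <- v %in% .AA20
    tb <- table(factor(v[std], levels = .AA20))
    res_counts[, "proteome"] <- res_counts[, "proteome"] + as.numeric(tb)
    if (any(dis)) {
      tbd <- table(factor(v[std & dis], levels = .AA20))
      res_counts[, "disordered"] <- res_counts[, "disordered"] + as.numeric(tbd)
    }
    if (L < n) next
    i1 <- seq_len(L - n + 1)
    valid <- std[i1] & std[i1 + 1] & std[i1 + 2]
    in_dis <- dis[i1] & dis[i1 + 1] & dis[i1 + 2]
    win_tot["proteome"] <- win_tot["proteome"] + sum(valid)
    win_tot["disordered"] <- win_tot["disordered"] + sum(valid & in_dis)
    centre <- factor(v[i1 + 1], levels = .AA20)
    for (f in seq_along(families)) {
      q <- families[[f]]
      hit <- valid & (v[i1] %in% q[[1]]) & (v[i1 + 2] %in% q[[3]]) &
        (v[i1 + 1] %in% q[[2]])
      if (!any(hit)) next
      tab <- table(centre[hit])
      obs[f, , "proteome"] <- obs[f, , "proteome"] + as.numeric(tab)
      if (any(hit & in_dis)) {
        tabd <- table(centre[hit & in_dis])
        obs[f, , "disordered"] <- obs[f, , "disordered"] + as.numeric(tabd)
      }
    }
  }
  obs[, , "structured"] <- obs[, , "proteome"] - obs[, , "disordered"]
  win_tot["structured"] <- win_tot["proteome"] - win_tot["disordered"]

  freq <- cbind(proteome = res_counts[, "proteome"] / sum(res_counts[, "proteome"]),
                disordered = if (sum(res_counts[, "disordered"]) > 0)
                  res_counts[, "disordered"] / sum(res_counts[, "disordered"])
                else rep(0, 20),
                structured = (res_counts[, "proteome"] - res_counts[, "disordered"]) /
                  max(sum(res_counts[, "proteome"]) - sum(res_counts[, "disordered"]), 1))
  rownames(freq) <- .AA20

  expd <- array(0, dim = dim(obs), dimnames = dimnames(obs))
  for (db in dbs) {
    for (f in seq_along(families)) {
      q <- families[[f]]
      for (x in .AA20) {
        qx <- q
        qx[[2]] <- x
        expd[f, x, db] <- expected_count(qx, freq[, db], win_tot[[db]])
      }
    }
  }
  structure(list(observed = obs, expected = expd,
                 window_totals = win_tot, frequencies = freq,
                 families = families),
            class = "census_result")
}

#' Total chi-squared over motif families and central residues
#'
#' `chi2_tot = sum_f sum_x (obs - exp)^2 / exp` over the 4 families x 20
#' central residues, with `nu = 80 - 4` degrees of freedom (one total
#' constraint per family) and an upper-tail p-value.
#'
#' @param observed,expected matrices (family x central residue), e.g. slices
#'   of a [census()] result.
#' @return List: `chi2_per_class` (per family), `chi2_tot`, `df`, `p_value`.
#' @export
chi_square_total <- function(observed, expected) {
  stopifnot(all(dim(observed) == dim(expected)))
  if (any(expected <= 0))
    stop("zero expected cell(s); merge or drop explicitly before testing")
  cells <- (observed - expected)^2 / expected
  chi2_tot <- sum(cells)
  df <- length(observed) - nrow(observed)
  list(chi2_per_class = rowSums(cells), chi2_tot = chi2_tot, df = df,
       p_value = pchisq(chi2_tot, df, lower.tail = FALSE))
}

#' Disordered-vs-structured enrichment profile
#'
#' For each central residue x: the percentage that x-centred motifs make up
#' of all disordered family matches, minus the same percentage among
#' structured matches. Positive means enrichment in disorder. Sums to zero.
#'
#' @param result a [census()] result.
#' @return Named numeric vector over the 20 residues (percentage points).
#' @export
enrichment_profile <- function(result) {
  stopifnot(inherits(result, "census_result"))
  d <- colSums(result$observed[, , "disordered", drop = FALSE][, , 1])
  s <- colSums(result$observed[, , "structured", drop = FALSE][, , 1])
  100 * (d / sum(d) - s / sum(s))
}

#' Interactors carrying a disordered motif
#'
#' Intersects a list of binder protein ids with the proteins that carry at
#' least one qualifying motif (default `[V/I]P[V/I]`) entirely inside a
#' disorder interval.
#'
#' @param binder_ids protein ids to screen.
#' @param proteome a [proteome_set()].
#' @param mask a [disorder_mask()].
#' @param query the required motif (default `[VI]P[VI]`).
#' @return data.frame `protein_id`, `n_motifs` for qualifying binders, with
#'   attribute `unknown_ids` listing ids absent from the proteome (also
#'   raised as a warning).
#' @export
intersect_interactors <- function(binder_ids, proteome, mask,
                                  query = slim_query("[VI]P[VI]")) {
  stopifnot(inherits(proteome, "proteome_set"))
  unknown <- setdiff(binder_ids, names(proteome$records))
  if (length(unknown))
    warning("unknown protein ids: ", paste(unknown, collapse = ", "))
  ids <- setdiff(binder_ids, unknown)
  n <- length(query)
  counts <- vapply(ids, function(id) {
    pos <- scan_motifs(proteome$records[[id]], query)
    if (!length(pos) || !id %in% names(mask)) return(0L)
    dis <- disorder_vector(nchar(proteome$records[[id]]), mask[[id]])
    sum(vapply(pos, function(p) all(dis[(p + 1):(p + n)]), logical(1)))
  }, integer(1))
  out <- data.frame(protein_id = ids[counts > 0],
                    n_motifs = unname(counts[counts > 0]),
                    stringsAsFactors = FALSE)
  attr(out, "unknown_ids") <- unknown
  out
}
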