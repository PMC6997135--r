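# Residue contact maps and the contact similarity / reduction-rate
# statistics used to compare the first and last snapshots of a run.

#' Residue contact map of one frame
#'
#' A pair of residues is in contact when the minimum heavy-atom distance
#' between them is below `cutoff` and their sequence separation is at
#' least `neighbor_exclusion`. Non-protein residues (heme, ligands,
#' solvent) are excluded by default. The spatial-grid path ("grid") and the
#' exhaustive path ("all_pairs") are interchangeable by construction.
#'
#' @param frame single-frame `trajectory` (or frame index into a longer
#'   one via `frame_index`).
#' @param cutoff contact distance cutoff in A (default 4.5).
#' @param neighbor_exclusion minimum |i - j| sequence separation
#'   (default 2; 0 disables).
#' @param include_het include non-protein residues (default FALSE).
#' @param calpha_only measure Cα-Cα distances instead of heavy-atom minima.
#' @param method "grid" (cell list) or "all_pairs".
#' @param frame_index which frame to map (default 1).
#' @return object of class `contact_map`: `contacts` (2-column matrix of
#'   residue ids, each row sorted), `residues`, `cutoff`,
#'   `neighbor_exclusion`, `n_skipped` (residues with no heavy atoms).
#' @export
contact_map <- function(frame, cutoff = 4.5, neighbor_exclusion = 2L,
                        include_het = FALSE, calpha_only = FALSE,
                        method = c("grid", "all_pairs"), frame_index = 1L) {
  method <- match.arg(method)
  topo <- frame$topology
  xyz <- frame_coords(frame, frame_index)
  aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
           "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL","HIE","HID",
           "HIP","CYX")
  keep <- topo$is_heavy
  if (!include_het) keep <- keep & topo$resname %in% aa3
  if (calpha_only) keep <- keep & topo$name == "CA"
  res_key <- paste(topo$chain, topo$resid, sep = "|")
  residues <- unique(res_key[if (include_het) rep(TRUE, nrow(topo)) else topo$resname %in% aa3])
  n_skipped <- sum(!residues %in% res_key[keep])
  atom_idx <- which(keep)
  if (!length(atom_idx)) stop("no heavy atoms available for contact mapping")
  pos <- xyz[atom_idx, , drop = FALSE]
  res_of_atom <- match(res_key[atom_idx], residues)
  seq_index <- match(residues, residues)  # position in residue order
  resid_of <- topo$resid[match(residues, res_key)]

  emit <- function(pairs_atoms) {
    # pairs_atoms: 2-column matrix of indices into atom_idx
    if (!nrow(pairs_atoms)) return(matrix(integer(0), ncol = 2))
    ri <- res_of_atom[pairs_atoms[, 1]]
    rj <- res_of_atom[pairs_atoms[, 2]]
    ok <- ri != rj & abs(ri - rj) >= neighbor_exclusion
    if (!any(ok)) return(matrix(integer(0), ncol = 2))
    p <- cbind(pmin(ri[ok], rj[ok]), pmax(ri[ok], rj[ok]))
    unique(p)
  }

  if (method == "all_pairs" || length(atom_idx) < 50L) {
    d <- as.matrix(dist(pos))
    hits <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
    contacts <- emit(hits)
  } else {
    # cell list at cutoff pitch; compare atoms in neighboring cells only
    cell <- floor(sweep(pos, 2, apply(pos, 2, min)) / cutoff)
    key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
    cells <- split(seq_len(nrow(pos)), key)
    coords_of <- function(k) as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    hits <- list()
    keys <- names(cells)
    keyset <- new.env(hash = TRUE)
    for (k in keys) assign(k, cells[[k]], envir = keyset)
    for (k in keys) {
      a <- cells[[k]]
      cc <- coords_of(k)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        nk <- paste(cc[1] + dx, cc[2] + dy, cc[3] + dz, sep = ",")
        if (!exists(nk, envir = keyset, inherits = FALSE)) next
        b <- get(nk, envir = keyset)
        if (nk < k) next          # each unordered cell pair once
        if (nk == k) {
          if (length(a) < 2L) next
          pr <- t(combn(a, 2L))
        } else {
          pr <- as.matrix(expand.grid(a, b))
        }
        dd <- sqrt(rowSums((pos[pr[, 1], , drop = FALSE] -
                            pos[pr[, 2], , drop = FALSE])^2))
        sel <- dd < cutoff
        if (any(sel)) hits[[length(hits) + 1L]] <- pr[sel, , drop = FALSE]
      }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else matrix(integer(0), ncol = 2)
    contacts <- emit(hits)
  }
  # report contacts as residue ids (as printed in the source file)
  cmat <- cbind(resid_of[contacts[, 1]], resid_of[contacts[, 2]])
  cmat <- cmat[order(cmat[, 1], cmat[, 2]), , drop = FALSE]
  structure(list(contacts = cmat, residues = resid_of, cutoff = cutoff,
                 neighbor_exclusion = neighbor_exclusion,
                 n_skipped = n_skipped),
            class = "contact_map")
}

contact_keys <- function(map) {
  if (!nrow(map$contacts)) return(character(0))
  paste(map$contacts[, 1], map$contacts[, 2], sep = "-")
}

#' Compare two contact maps
#'
#' Splits contacts into common and snapshot-specific sets and derives the
#' contact-similarity and reduction-rate statistics.
#'
#' @param first,last `contact_map` objects with identical cutoffs.
#' @return list of class `contact_comparison`: `common`, `specific_first`,
#'   `specific_last`, `total_first`, `total_last`, `similarity`,
#'   `reduction_rate`, plus the underlying pair sets.
#' @export
compare_maps <- function(first, last) {
  if (!isTRUE(all.equal(first$cutoff, last$cutoff)))
    stop("incompatible maps: cutoffs differ")
  a <- contact_keys(first)
  b <- contact_keys(last)
  common <- intersect(a, b)
  sf <- setdiff(a, b)
  sl <- setdiff(b, a)
  structure(list(common = length(common),
                 specific_first = length(sf),
                 specific_last = length(sl),
                 total_first = length(a),
                 total_last = length(b),
                 similarity = contact_similarity(length(common), length(sf),
                                                 length(sl)),
                 reduction_rate = if (length(a) > 0)
                   reduction_rate(length(sf), length(sl), length(a))
                 else NA_real_,
                 common_pairs = common, specific_first_pairs = sf,
                 specific_last_pairs = sl),
            class = "contact_comparison")
}

#' Contact similarity
#'
#' Common contacts divided by all contacts (common plus the contacts
#' specific to either snapshot). A conservation measure: 1 means the two
#' snapshots share every contact.
#'
#' @param common,specific_first,specific_last non-negative counts, not all
#'   zero.
#' @return fraction in [0, 1].
#' @export
contact_similarity <- function(common, specific_first, specific_last) {
  if (any(c(common, specific_first, specific_last) < 0))
    stop("counts must be >= 0")
  tot <- common + specific_first + specific_last
  if (tot == 0) stop("undefined similarity: all counts zero")
  common / tot
}

#' Contact reduction rate
#'
#' (first-specific - last-specific) / total contacts of the first
#' snapshot. Positive values indicate relaxation/expansion of the
#' structure over the run, negative values compaction.
#'
#' @param specific_first,specific_last non-negative counts.
#' @param total_first total contacts of the first snapshot (> 0).
#' @return signed fraction.
#' @export
reduction_rate <- function(specific_first, specific_last, total_first) {
  if (total_first <= 0) stop("undefined rate: total_first must be > 0")
  (specific_first - specific_last) / total_first
}

#' Per-segment specific-contact fractions
#'
#' Splits the residue range into consecutive segments of `segment_size`
#' residues (the final segment absorbs the remainder) and reports, for each
#' snapshot, the number of its specific contacts with at least one endpoint
#' in the segment divided by that snapshot's total contact count. A contact
#' spanning two segments counts once in each.
#'
#' @param first,last `contact_map` objects.
#' @param segment_size residues per segment (default 50).
#' @return data.frame: `segment`, `from`, `to`, `frac_first`, `frac_last`.
#' @export
segment_specific_fraction <- function(first, last, segment_size = 50L) {
  if (segment_size < 1L) stop("argument error: segment_size must be >= 1")
  cmp <- compare_maps(first, last)
  res_all <- sort(unique(c(first$residues, last$residues)))
  lo <- min(res_all); hi <- max(res_all)
  n_res <- hi - lo + 1L
  n_seg <- max(1L, n_res %/% segment_size)
  starts <- lo + (seq_len(n_seg) - 1L) * segment_size
  ends <- c(starts[-1L] - 1L, hi)
  split_pairs <- function(keys) {
    if (!length(keys)) return(matrix(integer(0), ncol = 2))
    do.call(rbind, lapply(strsplit(keys, "-", fixed = TRUE),
                          function(p) as.integer(p)))
  }
  sf <- split_pairs(cmp$specific_first_pairs)
  sl <- split_pairs(cmp$specific_last_pairs)
  count_in <- function(pairs, a, b) {
    if (!nrow(pairs)) return(0L)
    sum((pairs[, 1] >= a & pairs[, 1] <= b) |
        (pairs[, 2] >= a & pairs[, 2] <= b))
  }
  data.frame(segment = seq_len(n_seg), from = starts, to = ends,
             frac_first = vapply(seq_len(n_seg), function(s)
               if (cmp$total_first > 0)
                 count_in(sf, starts[s], ends[s]) / cmp$total_first else 0,
               numeric(1)),
             frac_last = vapply(seq_len(n_seg), function(s)
               if (cmp$total_last > 0)
                 count_in(sl, starts[s], ends[s]) / cmp$total_last else 0,
               numeric(1)))
}
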