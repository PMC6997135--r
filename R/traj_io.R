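#' @importFrom stats cor sd setNames rnorm runif var dist cov
#' @importFrom utils head tail write.csv combn
NULL

# Units: coordinates in Angstrom, energies kJ/mol, time ns.
# Atom indices are 0-free: topology rows are addressed 1-based (R convention);
# residue indices are kept exactly as printed in the source file.

ELEMENT_VDW <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, FE = 2.0,
                 P = 1.8, NA. = 2.27, CL = 1.75)
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, FE = 55.845, NA. = 22.99, CL = 35.45)

KNOWN_ELEMENTS <- c("H", "C", "N", "O", "S", "P", "FE", "NA", "CL", "MG",
                    "ZN", "K", "CA", "MN", "CU", "BR", "I", "F", "SE")

#' Construct a trajectory object
#'
#' A trajectory is one topology (an atom table) shared by an ordered set of
#' coordinate frames. Coordinates are stored as an `n_atoms x 3 x n_frames`
#' array in Angstrom.
#'
#' @param topology data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `occupancy`, `bfactor`, `is_heavy`.
#' @param coords numeric array `n_atoms x 3 x n_frames` (a single
#'   `n_atoms x 3` matrix is promoted to one frame).
#' @param times optional per-frame times in ns; must strictly increase.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (nrow(topology) != dim(coords)[1])
    stop("coordinate count does not match topology atom count")
  if (dim(coords)[3] < 1L) stop("trajectory needs at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(times)) {
    if (length(times) != dim(coords)[3])
      stop("times length does not match frame count")
    if (any(diff(times) <= 0)) stop("frame times must strictly increase")
  }
  dup <- duplicated(topology[, c("chain", "resid", "name")])
  if (any(dup))
    stop("duplicate (chain, residue_index, name) in topology: ",
         paste(topology$name[dup][1], topology$resid[dup][1]))
  structure(list(topology = topology, coords = coords, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, %d residues\n",
              n_atoms(x), n_frames(x),
              nrow(unique(x$topology[, c("chain", "resid")]))))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a `trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame's coordinates
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` coordinate matrix.
#' @export
frame_coords <- function(traj, i = 1L) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  traj$coords[, , i, drop = TRUE]
}

guess_element <- function(name, resname) {
  nm <- toupper(trimws(name))
  nm2 <- gsub("[0-9']", "", nm)
  if (nchar(nm2) >= 2 && substr(nm2, 1, 2) %in% c("FE", "CL", "BR", "MG",
                                                  "ZN", "SE", "NA", "MN"))
    return(substr(nm2, 1, 2))
  # PDB convention: names starting with a digit (e.g. 1HB) are hydrogens
  if (grepl("^[0-9]", nm)) return("H")
  substr(nm2, 1, 1)
}

parse_atom_line <- function(line) {
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  line <- pad(line, 80)
  el <- toupper(trimws(substr(line, 77, 78)))
  name <- trimws(substr(line, 13, 16))
  resname <- trimws(substr(line, 18, 20))
  if (el == "") el <- guess_element(name, resname)
  occ <- suppressWarnings(as.numeric(substr(line, 55, 60)))
  bf <- suppressWarnings(as.numeric(substr(line, 61, 66)))
  list(serial = suppressWarnings(as.integer(substr(line, 7, 11))),
       name = name,
       altloc = substr(line, 17, 17),
       resname = resname,
       chain = substr(line, 22, 22),
       resid = suppressWarnings(as.integer(substr(line, 23, 26))),
       x = as.numeric(substr(line, 31, 38)),
       y = as.numeric(substr(line, 39, 46)),
       z = as.numeric(substr(line, 47, 54)),
       occupancy = if (is.na(occ)) 1 else occ,
       bfactor = if (is.na(bf)) 0 else bf,
       element = el)
}

#' Read a (multi-model) PDB file
#'
#' Parses fixed-column ATOM/HETATM records. Each MODEL/ENDMDL block becomes
#' one frame; a file without MODEL records yields a single frame. Alternate
#' locations are resolved by keeping the highest-occupancy variant (ties:
#' first encountered). TER/END records are tolerated.
#'
#' @param file path to a PDB file, or its content as a character vector of
#'   lines when `text = TRUE`.
#' @param text logical; treat `file` as content rather than a path.
#' @return a `trajectory`.
#' @export
read_pdb <- function(file, text = FALSE) {
  lines <- if (text) {
    if (length(file) == 1L) strsplit(file, "\n", fixed = TRUE)[[1]] else file
  } else readLines(file, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty structure: no ATOM/HETATM records")
  model_id <- cumsum(substr(rec, 1, 5) == "MODEL")
  if (max(model_id) == 0L) model_id <- model_id + 1L
  model_of_atom <- model_id[is_atom]
  model_of_atom[model_of_atom == 0L] <- 1L
  parsed <- lapply(lines[is_atom], parse_atom_line)
  df <- data.frame(
    serial = vapply(parsed, `[[`, integer(1), "serial"),
    name = vapply(parsed, `[[`, character(1), "name"),
    altloc = vapply(parsed, `[[`, character(1), "altloc"),
    resname = vapply(parsed, `[[`, character(1), "resname"),
    chain = vapply(parsed, `[[`, character(1), "chain"),
    resid = vapply(parsed, `[[`, integer(1), "resid"),
    x = vapply(parsed, `[[`, numeric(1), "x"),
    y = vapply(parsed, `[[`, numeric(1), "y"),
    z = vapply(parsed, `[[`, numeric(1), "z"),
    occupancy = vapply(parsed, `[[`, numeric(1), "occupancy"),
    bfactor = vapply(parsed, `[[`, numeric(1), "bfactor"),
    element = vapply(parsed, `[[`, character(1), "element"),
    model = model_of_atom,
    stringsAsFactors = FALSE)

  resolve_altloc <- function(m) {
    key <- paste(m$chain, m$resid, m$name, sep = "|")
    keep <- rep(TRUE, nrow(m))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[which.max(m$occupancy[idx])]  # ties: first (which.max)
      keep[setdiff(idx, best)] <- FALSE
    }
    m[keep, , drop = FALSE]
  }
  models <- lapply(split(df, df$model), resolve_altloc)
  n0 <- nrow(models[[1]])
  for (i in seq_along(models)) {
    if (nrow(models[[i]]) != n0)
      stop(sprintf("model mismatch: model %s has %d atoms, model 1 has %d",
                   names(models)[i], nrow(models[[i]]), n0))
  }
  m1 <- models[[1]]
  topo <- data.frame(serial = m1$serial, name = m1$name,
                     element = ifelse(m1$element %in% KNOWN_ELEMENTS,
                                      m1$element, "X"),
                     resname = m1$resname, resid = m1$resid,
                     chain = m1$chain, occupancy = m1$occupancy,
                     bfactor = m1$bfactor,
                     is_heavy = m1$element != "H",
                     stringsAsFactors = FALSE)
  coords <- array(0, dim = c(n0, 3, length(models)))
  for (i in seq_along(models))
    coords[, , i] <- as.matrix(models[[i]][, c("x", "y", "z")])
  trajectory(topo, coords)
}

#' Write a trajectory as (multi-model) PDB text
#'
#' Fixed-column output, coordinates to 3 decimals; trajectories with more
#' than one frame are written as numbered MODEL/ENDMDL blocks. Output is
#' byte-stable for identical input.
#'
#' @param traj a `trajectory`.
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @return character vector of PDB lines (invisibly when writing a file).
#' @export
write_pdb <- function(traj, file = NULL) {
  if (max(abs(traj$coords)) >= 1e4)
    stop("format overflow: coordinate magnitude >= 10,000 A")
  topo <- traj$topology
  multi <- n_frames(traj) > 1L
  fmt_name <- function(nm, el) {
    # element-aligned atom-name column (cols 13-16)
    if (nchar(nm) >= 4L || nchar(el) == 2L) formatC(nm, width = -4)
    else paste0(" ", formatC(nm, width = -3))
  }
  out <- character(0)
  for (f in seq_len(n_frames(traj))) {
    xyz <- matrix(traj$coords[, , f], ncol = 3L)
    lines <- sprintf(
      "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      topo$serial, mapply(fmt_name, topo$name, topo$element),
      topo$resname, topo$chain, topo$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], topo$occupancy, topo$bfactor,
      topo$element)
    if (multi) lines <- c(sprintf("MODEL     %4d", f), lines, "ENDMDL")
    out <- c(out, lines)
  }
  out <- c(out, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read a per-atom parameter table
#'
#' Tab- or whitespace-delimited text with header
#' `chain residue_index atom_name charge lj_sigma lj_epsilon vdw_radius`
#' (charge in elementary units, sigma/radius in Angstrom, epsilon in
#' kJ/mol). Keys must be unique; `lj_sigma > 0`, `lj_epsilon >= 0`,
#' `vdw_radius > 0`.
#'
#' @param file path or content lines (`text = TRUE`).
#' @param text logical; treat `file` as content.
#' @return data.frame of class `topology_table`.
#' @export
read_topology_table <- function(file, text = FALSE) {
  lines <- if (text) {
    if (length(file) == 1L) strsplit(file, "\n", fixed = TRUE)[[1]] else file
  } else readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  need <- c("chain", "residue_index", "atom_name", "charge", "lj_sigma",
            "lj_epsilon", "vdw_radius")
  hdr <- strsplit(trimws(lines[1]), "[\t ]+")[[1]]
  missing_col <- setdiff(need, hdr)
  if (length(missing_col))
    stop("schema error: missing column(s) ", paste(missing_col, collapse = ", "))
  rows <- lapply(seq_along(lines[-1]), function(i) {
    fields <- strsplit(trimws(lines[i + 1]), "[\t ]+")[[1]]
    if (length(fields) != length(hdr))
      stop(sprintf("parse error at row %d: %d fields, expected %d",
                   i, length(fields), length(hdr)))
    setNames(as.list(fields), hdr)
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r$chain,
               residue_index = suppressWarnings(as.integer(r$residue_index)),
               atom_name = r$atom_name,
               charge = suppressWarnings(as.numeric(r$charge)),
               lj_sigma = suppressWarnings(as.numeric(r$lj_sigma)),
               lj_epsilon = suppressWarnings(as.numeric(r$lj_epsilon)),
               vdw_radius = suppressWarnings(as.numeric(r$vdw_radius)),
               stringsAsFactors = FALSE)))
  num_cols <- c("residue_index", "charge", "lj_sigma", "lj_epsilon",
                "vdw_radius")
  for (cn in num_cols) {
    bad <- which(is.na(tab[[cn]]))
    if (length(bad))
      stop(sprintf("parse error at row %d: non-numeric %s", bad[1], cn))
  }
  bad <- which(tab$lj_sigma <= 0 | tab$lj_epsilon < 0 | tab$vdw_radius <= 0)
  if (length(bad))
    stop(sprintf("invariant violation at row %d: require lj_sigma > 0, lj_epsilon >= 0, vdw_radius > 0",
                 bad[1]))
  key <- paste(tab$chain, tab$residue_index, tab$atom_name, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate key: ", key[duplicated(key)][1])
  class(tab) <- c("topology_table", "data.frame")
  tab
}

#' Look up per-atom parameters for a trajectory
#' @param traj a `trajectory`.
#' @param table a `topology_table`.
#' @param sel atom indices (default all).
#' @return data.frame with one parameter row per selected atom.
#' @export
match_parameters <- function(traj, table, sel = seq_len(n_atoms(traj))) {
  key_t <- paste(traj$topology$chain[sel], traj$topology$resid[sel],
                 traj$topology$name[sel], sep = "|")
  key_p <- paste(table$chain, table$residue_index, table$atom_name, sep = "|")
  idx <- match(key_t, key_p)
  if (anyNA(idx)) {
    missing_atom <- which(is.na(idx))[1]
    stop("missing parameter for atom ", key_t[missing_atom])
  }
  table[idx, , drop = FALSE]
}

# ---- atom selection grammar ------------------------------------------------
# terms: name <NM>, resname <RN>, resid <a>[-<b>], chain <C>, heavy, calpha
# combined with and/or/not and parentheses.

tokenize_selection <- function(expr) {
  pat <- "\\(|\\)|[^() \t]+"
  m <- gregexpr(pat, expr)[[1]]
  if (m[1] == -1) stop("grammar error at position 1: empty expression")
  data.frame(tok = regmatches(expr, gregexpr(pat, expr))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

#' Select atoms with a small expression grammar
#'
#' Supported terms: `name <NAME>`, `resname <RES>`, `resid <a>` or
#' `resid <a>-<b>`, `chain <C>`, `heavy` (non-hydrogen), `calpha` (alias
#' `ca`, Cα atoms), `protein`, `all`; combined with `and`, `or`, `not` and
#' parentheses. Matching is case-insensitive for keywords, exact for values.
#'
#' @param traj a `trajectory`.
#' @param expr selection expression, e.g. `"resid 360-381 and name CA"`.
#' @return sorted integer vector of topology indices (possibly empty).
#' @export
select_atoms <- function(traj, expr) {
  topo <- traj$topology
  toks <- tokenize_selection(expr)
  i <- 1L
  n <- nrow(toks)
  peek <- function() if (i <= n) tolower(toks$tok[i]) else ""
  err <- function(msg) stop(sprintf("grammar error at position %d: %s",
                                    if (i <= n) toks$pos[i] else nchar(expr) + 1L, msg))
  take <- function() { t <- toks$tok[i]; i <<- i + 1L; t }

  aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
           "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL","HIE","HID",
           "HIP","CYX")

  parse_primary <- function() {
    kw <- peek()
    if (kw == "(") {
      take()
      v <- parse_or()
      if (peek() != ")") err("expected ')'")
      take()
      return(v)
    }
    if (kw == "not") { take(); return(!parse_primary()) }
    if (kw == "heavy") { take(); return(topo$is_heavy) }
    if (kw %in% c("calpha", "ca")) {
      take()
      return(topo$name == "CA" & topo$resname %in% aa3)
    }
    if (kw == "protein") { take(); return(topo$resname %in% aa3) }
    if (kw == "all") { take(); return(rep(TRUE, nrow(topo))) }
    if (kw %in% c("name", "resname", "chain", "resid")) {
      take()
      if (i > n) err(paste("missing value after", kw))
      val <- take()
      if (kw == "name") return(topo$name == val)
      if (kw == "resname") return(topo$resname == val)
      if (kw == "chain") return(topo$chain == val)
      if (grepl("^-?[0-9]+--?[0-9]+$", val)) {
        parts <- regmatches(val, regexec("^(-?[0-9]+)-(-?[0-9]+)$", val))[[1]]
        lo <- as.integer(parts[2]); hi <- as.integer(parts[3])
        return(topo$resid >= lo & topo$resid <= hi)
      }
      if (!grepl("^-?[0-9]+$", val)) err("resid expects an integer or range")
      return(topo$resid == as.integer(val))
    }
    err(paste0("unknown term '", toks$tok[i], "'"))
  }
  parse_and <- function() {
    v <- parse_primary()
    while (peek() == "and") { take(); v <- v & parse_primary() }
    v
  }
  parse_or <- function() {
    v <- parse_and()
    while (peek() == "or") { take(); v <- v | parse_and() }
    v
  }
  v <- parse_or()
  if (i <= n) err("unexpected trailing input")
  which(v)
}
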