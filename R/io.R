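# Structure and ddG input: PDB reading (via bio3d), interface detection by
# heavy-atom contact, the structural exclusion filters, and joining of
# externally computed alanine-scan ddG tables onto interface residues.

.is_heavy <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    sy <- toupper(trimws(as.character(elesy)))
    known <- !is.na(sy) & nzchar(sy)
    out <- logical(length(elety))
    out[known] <- !(sy[known] %in% c("H", "D"))
    if (any(!known)) {
      # fall back to the atom-name convention: hydrogens are "H*", "1H*", ...
      out[!known] <- !grepl("^[0-9]*[HD]", toupper(trimws(elety[!known])))
    }
    out
  } else {
    !grepl("^[0-9]*[HD]", toupper(trimws(elety)))
  }
}

#' Read a PDB structure for interface analysis
#'
#' Parses a PDB file (through [bio3d::read.pdb()]) and reduces it to the
#' per-residue representation used by the interface pipeline: one record per
#' `(chain, resseq, icode)` that has a C-alpha atom.  Alternate locations are
#' collapsed to the highest-occupancy copy (ties broken by altloc label), and
#' residues lacking a C-alpha are dropped with a warning.  HETATM groups are
#' retained separately so that the heteroatom exclusion filter can inspect
#' them.
#'
#' @param path Path to a PDB file.
#' @param model Model number to use for multi-model files (default 1, the
#'   first model).
#' @return An object of class `ecr_structure`: a list with elements `atoms`
#'   (protein ATOM records, one row per atom), `het` (HETATM records),
#'   `residues` (one row per protein residue with C-alpha coordinates and a
#'   `backbone_complete` flag), and `pdb_id` (file basename).
#' @seealso [find_interface()], [read_ddg_table()]
#' @export
read_structure <- function(path, model = 1L) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_input("structure file not found: ", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = model > 1L, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop_input("cannot parse PDB file '", path, "': ",
                                   conditionMessage(e)))
  atom <- pdb$atom
  if (model > 1L) {
    nmod <- nrow(pdb$xyz)
    if (is.null(nmod) || nmod < model) {
      stop_input("model ", model, " requested but file has ",
                 max(1L, nmod %||% 1L), " model(s)")
    }
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    atom$x <- xyz[, 1L]; atom$y <- xyz[, 2L]; atom$z <- xyz[, 3L]
  }

  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  atom$chain[is.na(atom$chain)] <- " "
  occ <- atom$o
  occ[!is.finite(occ)] <- 1

  # altloc collapse: keep the highest-occupancy copy of each atom
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  ord <- order(key, -occ, atom$alt)
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(key[ord]), , drop = FALSE]

  atom$is_heavy <- .is_heavy(atom$elety, atom$elesy)

  is_protein <- atom$type == "ATOM"
  prot <- atom[is_protein, , drop = FALSE]
  het <- atom[!is_protein, , drop = FALSE]
  if (nrow(prot) == 0L) stop_input("no protein (ATOM) residues in '", path, "'")

  rkey <- paste(prot$chain, prot$resno, prot$insert, sep = "\r")
  first <- !duplicated(rkey)
  res <- data.frame(chain = prot$chain[first],
                    resseq = prot$resno[first],
                    icode = prot$insert[first],
                    resname = prot$resid[first],
                    stringsAsFactors = FALSE)
  rid <- rkey[first]
  ca <- prot[prot$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  m <- match(rid, ca_key)
  res$x <- ca$x[m]; res$y <- ca$y[m]; res$z <- ca$z[m]

  bb <- vapply(split(prot$elety, rkey)[rid], function(e) {
    all(c("N", "CA", "C", "O") %in% e)
  }, logical(1L))
  res$backbone_complete <- unname(bb)
  res$nonstandard <- !(res$resname %in% STANDARD_AA)

  no_ca <- is.na(res$x)
  if (any(no_ca)) {
    warning(sum(no_ca), " residue(s) without a C-alpha dropped from '",
            basename(path), "'", call. = FALSE)
    keep_keys <- rid[!no_ca]
    prot <- prot[rkey %in% keep_keys, , drop = FALSE]
    res <- res[!no_ca, , drop = FALSE]
  }
  rownames(res) <- NULL

  structure(list(path = path,
                 pdb_id = tools::file_path_sans_ext(basename(path)),
                 atoms = prot,
                 het = het,
                 residues = res),
            class = "ecr_structure")
}

#' @export
print.ecr_structure <- function(x, ...) {
  cat("PDB structure '", x$pdb_id, "': ", nrow(x$residues),
      " residues in chain(s) ", paste(sort(unique(x$residues$chain)),
                                      collapse = ", "),
      "; ", nrow(x$het), " HETATM record(s)\n", sep = "")
  invisible(x)
}

# squared cross-distances between two coordinate matrices (n x 3, m x 3)
.cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Identify the pairwise chain-chain interface of a structure
#'
#' A residue of `chain_a` is interfacial when any of its heavy (non-hydrogen)
#' atoms lies within `cutoff` angstroms of any heavy atom of `chain_b`, and
#' symmetrically.  The returned interface holds the union of interfacial
#' residues from both chains, each with its C-alpha coordinates.  Heteroatom
#' groups other than water and simple monoatomic ions lying within `cutoff`
#' of an interface atom are flagged for the exclusion filter.
#'
#' @param structure An `ecr_structure` from [read_structure()].
#' @param chain_a,chain_b Chain identifiers (single characters).
#' @param cutoff Heavy-atom contact distance in angstroms (default 4.0).
#' @return An object of class `ecr_interface` with elements `id`
#'   (`"<pdbid>_<A><B>"`), `chain_a`, `chain_b`, `cutoff`, `residues` (data
#'   frame: chain, resseq, icode, resname, C-alpha x/y/z, backbone_complete,
#'   `ddg` initialised to `NA`), `het_near` (logical) and `het_near_names`,
#'   plus `category`/`subcategory` set to `"unknown"`.
#' @export
find_interface <- function(structure, chain_a, chain_b, cutoff = 4.0) {
  stopifnot(inherits(structure, "ecr_structure"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop_input("cutoff must be a positive distance in angstroms")
  }
  atoms <- structure$atoms
  for (ch in c(chain_a, chain_b)) {
    if (!any(atoms$chain == ch)) stop_input("chain '", ch, "' not present in structure")
  }

  ha <- atoms[atoms$chain == chain_a & atoms$is_heavy, , drop = FALSE]
  hb <- atoms[atoms$chain == chain_b & atoms$is_heavy, , drop = FALSE]
  xa <- as.matrix(ha[, c("x", "y", "z")])
  xb <- as.matrix(hb[, c("x", "y", "z")])
  c2 <- cutoff^2
  if (is.finite(cutoff)) {
    d2 <- .cross_dist2(xa, xb)
    in_a <- apply(d2 <= c2, 1L, any)
    in_b <- apply(d2 <= c2, 2L, any)
  } else {
    in_a <- rep(TRUE, nrow(ha)); in_b <- rep(TRUE, nrow(hb))
  }

  key_a <- unique(paste(ha$chain, ha$resno, ha$insert, sep = "\r")[in_a])
  key_b <- unique(paste(hb$chain, hb$resno, hb$insert, sep = "\r")[in_b])
  res <- structure$residues
  rkey <- paste(res$chain, res$resseq, res$icode, sep = "\r")
  members <- res[rkey %in% c(key_a, key_b), , drop = FALSE]
  rownames(members) <- NULL
  members$ddg <- rep(NA_real_, nrow(members))

  # heteroatom contact with the interface (excluding water and simple ions)
  het <- structure$het
  het_bad <- het[het$is_heavy &
                   !(het$resid %in% c(WATER_RESID, SIMPLE_IONS)), , drop = FALSE]
  het_near <- FALSE
  het_names <- character(0)
  if (nrow(het_bad) > 0L && nrow(members) > 0L && is.finite(cutoff)) {
    mk <- paste(members$chain, members$resseq, members$icode, sep = "\r")
    iat <- atoms[atoms$is_heavy &
                   paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r") %in% mk,
                 , drop = FALSE]
    d2h <- .cross_dist2(as.matrix(het_bad[, c("x", "y", "z")]),
                        as.matrix(iat[, c("x", "y", "z")]))
    hit <- apply(d2h <= c2, 1L, any)
    het_near <- any(hit)
    het_names <- sort(unique(het_bad$resid[hit]))
  }

  structure(list(id = paste0(structure$pdb_id, "_", chain_a, chain_b),
                 pdb_id = structure$pdb_id,
                 chain_a = chain_a, chain_b = chain_b, cutoff = cutoff,
                 residues = members,
                 category = "unknown", subcategory = "unknown",
                 het_near = het_near, het_near_names = het_names),
            class = "ecr_interface")
}

#' @export
print.ecr_interface <- function(x, ...) {
  n_ddg <- sum(is.finite(x$residues$ddg))
  cat("Interface ", x$id, " (chains ", x$chain_a, "/", x$chain_b,
      ", cutoff ", x$cutoff, " A): ", nrow(x$residues), " residues, ",
      n_ddg, " with ddG; category ", x$category, "\n", sep = "")
  invisible(x)
}

#' Apply the structural exclusion filters to an interface
#'
#' Implements the dataset-curation rules: interfaces with two or fewer
#' residues are rejected (a linear fit of energy against centrality needs at
#' least three points), as are interfaces contacted by heteroatoms other than
#' water or simple ions, and interfaces containing disordered residues
#' (incomplete backbone).
#'
#' @param interface An `ecr_interface`.
#' @param heteroatoms_near Optional logical override for the heteroatom
#'   contact flag; defaults to the flag recorded by [find_interface()].
#' @return A list with `keep` (logical) and `reason` (string; `""` if kept).
#' @export
apply_exclusion_filters <- function(interface, heteroatoms_near = NULL) {
  stopifnot(inherits(interface, "ecr_interface"))
  n <- nrow(interface$residues)
  if (n <= 2L) {
    return(list(keep = FALSE, reason = "2 or fewer residues in the interface"))
  }
  het <- heteroatoms_near %||% isTRUE(interface$het_near)
  if (isTRUE(het)) {
    nm <- paste(interface$het_near_names, collapse = ", ")
    return(list(keep = FALSE,
                reason = paste0("heteroatom (non-water, non-simple-ion) in the interface",
                                if (nzchar(nm)) paste0(": ", nm) else "")))
  }
  if (any(!interface$residues$backbone_complete)) {
    return(list(keep = FALSE,
                reason = "disordered residue(s) (incomplete backbone) in the interface"))
  }
  list(keep = TRUE, reason = "")
}

#' Read a per-residue alanine-scan ddG table
#'
#' Reads a whitespace- or tab-separated table of per-residue ddG values (in
#' kcal/mol) as produced by an external computational alanine scanning run.
#' The expected columns are `chain`, `res`, `icode`, `resname`, `ddg`;
#' alternative dialects (e.g. Robetta-style listings) are accommodated by
#' `column_map`, a named character vector mapping the canonical names to the
#' file's column names.
#'
#' @param path Path to the table.
#' @param column_map Optional named character vector, e.g.
#'   `c(chain = "chainid", res = "pdbres", ddg = "DG_binding")`.  `icode` and
#'   `resname` are optional in the file.
#' @return An object of class `ecr_ddg_table`: a data frame with columns
#'   `chain`, `resseq`, `icode`, `ddg` (and `resname` when available), one
#'   row per residue; keys are checked for uniqueness and values for
#'   finiteness.
#' @export
read_ddg_table <- function(path, column_map = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_input("ddG table not found: ", path)
  }
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      comment.char = "#", check.names = FALSE),
    error = function(e) stop_input("cannot read ddG table '", path, "': ",
                                   conditionMessage(e)))
  nm <- function(std, default = std) {
    cm <- column_map[std]
    if (!is.null(column_map) && !is.na(cm)) unname(cm) else default
  }
  need <- c(chain = nm("chain"), res = nm("res"), ddg = nm("ddg"))
  miss <- need[!(need %in% names(tab))]
  if (length(miss) > 0L) {
    stop_input("ddG table is missing required column(s): ",
               paste(miss, collapse = ", "))
  }
  icol <- nm("icode")
  out <- data.frame(chain = as.character(tab[[need["chain"]]]),
                    resseq = as.integer(tab[[need["res"]]]),
                    icode = if (icol %in% names(tab))
                      as.character(tab[[icol]]) else "",
                    stringsAsFactors = FALSE)
  out$icode[is.na(out$icode) | out$icode == "-"] <- ""
  rcol <- nm("resname")
  if (rcol %in% names(tab)) out$resname <- as.character(tab[[rcol]])
  ddg <- tab[[need["ddg"]]]
  if (!is.numeric(ddg)) {
    ddg <- suppressWarnings(as.numeric(ddg))
  }
  if (any(!is.finite(ddg))) stop_input("non-numeric or non-finite ddG value(s) in '", path, "'")
  out$ddg <- as.numeric(ddg)
  key <- paste(out$chain, out$resseq, out$icode, sep = "\r")
  if (anyDuplicated(key)) {
    d <- out[duplicated(key), c("chain", "resseq"), drop = FALSE][1L, ]
    stop_input("duplicate ddG key for chain ", d$chain, " residue ", d$resseq)
  }
  class(out) <- c("ecr_ddg_table", "data.frame")
  out
}

#' Attach ddG values to the residues of an interface
#'
#' Joins a ddG table onto interface residues by `(chain, resseq, icode)`.
#' Native glycine and proline are always assigned a missing ddG (they are not
#' alanine-scanned), regardless of table content.  Geometry is never altered
#' and the operation is idempotent; join statistics are recorded in the
#' `"join_stats"` attribute.
#'
#' @param interface An `ecr_interface`.
#' @param table An `ecr_ddg_table` from [read_ddg_table()].
#' @return The interface with `residues$ddg` filled where a key matched.
#' @export
attach_ddg <- function(interface, table) {
  stopifnot(inherits(interface, "ecr_interface"),
            inherits(table, "ecr_ddg_table"))
  res <- interface$residues
  rkey <- paste(res$chain, res$resseq, res$icode, sep = "\r")
  tkey <- paste(table$chain, table$resseq, table$icode, sep = "\r")
  m <- match(rkey, tkey)
  res$ddg <- table$ddg[m]
  masked <- res$resname %in% c("GLY", "PRO")
  res$ddg[masked] <- NA_real_
  interface$residues <- res
  attr(interface, "join_stats") <- list(
    matched = sum(!is.na(m) & !masked),
    unmatched = sum(is.na(m) & !masked),
    masked_glypro = sum(masked))
  interface
}
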