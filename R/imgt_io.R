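#' IMGT region definitions for TCR/antibody variable domains
#'
#' Anchor and loop residue numbers for the three CDRs under IMGT numbering.
#' Anchors are the six framework positions flanking each loop on either side;
#' structures are superposed on anchor backbone atoms before loop RMSD is
#' measured.
#'
#' @return A named list with elements `CDR1`, `CDR2`, `CDR3`, each a list with
#'   integer vectors `anchors` and `loop` (inclusive IMGT positions).
#' @export
#' @examples
#' region_definitions()$CDR3$loop   # 106:117
region_definitions <- function() {
  list(
    CDR1 = list(anchors = c(22:27, 39:44), loop = 28:38),
    CDR2 = list(anchors = c(51:56, 66:71), loop = 57:65),
    CDR3 = list(anchors = c(100:105, 118:123), loop = 106:117)
  )
}

#' Canonical IMGT sort key for (position, insertion code) pairs
#'
#' Within position 111 insertion codes ascend (111, 111A, 111B, ...); within
#' position 112 they descend (..., 112B, 112A, 112). This is the IMGT CDR3
#' gap-filling convention: insertions grow from both sides towards the top of
#' the loop.
#'
#' @param imgt integer IMGT positions
#' @param icode insertion codes ("" for none)
#' @return numeric sort key (ascending = canonical order)
#' @export
imgt_sort_key <- function(imgt, icode = "") {
  icode <- as.character(icode)
  icode[is.na(icode)] <- ""
  r <- match(icode, LETTERS)
  r[is.na(r)] <- 0L
  frac <- ifelse(imgt == 112, ifelse(r == 0L, 0, -r), r)
  imgt + frac / 100
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a chain structure
#'
#' An IMGT-numbered variable-domain chain: backbone atoms keyed by
#' (IMGT position, insertion code, atom name). Atoms are re-ordered into
#' canonical IMGT order regardless of input order; duplicate keys are an
#' integrity error. Absent backbone atoms are simply missing rows, never
#' fabricated.
#'
#' @param chain_kind one of "alpha", "beta", "heavy", "light"
#' @param atoms data.frame with columns `imgt` (integer), `icode` (character,
#'   "" for none), `aa` (one-letter code), `atom` (N/CA/C/O), `x`, `y`, `z`
#'   (Angstrom)
#' @param v_gene,j_gene optional gene labels
#' @param species optional species tag (e.g. "H-" human, "M-" murine prefix
#'   convention)
#' @return object of class `chain_structure`
#' @export
chain_structure <- function(chain_kind, atoms, v_gene = NA_character_,
                            j_gene = NA_character_, species = NA_character_) {
  chain_kind <- match.arg(chain_kind, c("alpha", "beta", "heavy", "light"))
  need <- c("imgt", "icode", "aa", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop_with("usage_error", "atoms must have columns imgt, icode, aa, atom, x, y, z")
  }
  atoms$icode <- as.character(atoms$icode)
  atoms$icode[is.na(atoms$icode)] <- ""
  if (any(atoms$imgt < 1)) stop_with("integrity_error", "IMGT numbers must be >= 1")
  if (!all(atoms$atom %in% BACKBONE_ATOMS)) {
    stop_with("usage_error", "only backbone atoms N, CA, C, O are supported")
  }
  bad <- !(atoms$aa %in% c(AA20, "X"))
  if (any(bad)) atoms$aa[bad] <- "X"
  key <- paste(atoms$imgt, atoms$icode, atoms$atom)
  if (anyDuplicated(key)) {
    stop_with("integrity_error", sprintf(
      "duplicate (imgt, icode, atom) within chain: %s",
      key[duplicated(key)][1]))
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop_with("integrity_error", "non-finite backbone coordinates")
  }
  ord <- order(imgt_sort_key(atoms$imgt, atoms$icode),
               match(atoms$atom, BACKBONE_ATOMS))
  atoms <- atoms[ord, need, drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(chain_kind = chain_kind, atoms = atoms,
                 v_gene = v_gene, j_gene = j_gene, species = species),
            class = "chain_structure")
}

#' Construct a paired-chain record
#'
#' A paired variable-domain structure: TCR alpha/beta or antibody
#' light/heavy. The `alpha` slot holds the alpha (or light) chain and the
#' `beta` slot the beta (or heavy) chain.
#'
#' @param record_id identifier string
#' @param alpha,beta `chain_structure` objects
#' @param source free-text provenance tag (e.g. file of origin)
#' @return object of class `tcr_record`
#' @export
tcr_record <- function(record_id, alpha, beta, source = "") {
  stopifnot(inherits(alpha, "chain_structure"), inherits(beta, "chain_structure"))
  ok <- (alpha$chain_kind == "alpha" && beta$chain_kind == "beta") ||
        (alpha$chain_kind == "light" && beta$chain_kind == "heavy")
  if (!ok) {
    stop_with("usage_error",
              "record chains must be (alpha, beta) or (light, heavy)")
  }
  structure(list(record_id = record_id, alpha = alpha, beta = beta,
                 source = source), class = "tcr_record")
}

#' @export
print.tcr_record <- function(x, ...) {
  cat(sprintf("<tcr_record %s: %s chain %d res / %s chain %d res>\n",
              x$record_id,
              x$alpha$chain_kind, nrow(unique(x$alpha$atoms[c("imgt", "icode")])),
              x$beta$chain_kind, nrow(unique(x$beta$atoms[c("imgt", "icode")]))))
  invisible(x)
}

#' Read an IMGT-numbered variable-domain structure from PDB
#'
#' The residue-sequence field must carry IMGT positions (the convention of
#' STCRDab and of deposited prediction sets); insertion codes live in the
#' icode field. Chain identity is never inferred from sequence: an explicit
#' `chain_map` names which file chains are which.
#'
#' @param path PDB file
#' @param chain_map named character vector mapping file chain identifiers to
#'   chain kinds, e.g. `c(A = "alpha", B = "beta")`
#' @param record_id identifier for the record; defaults to the file base name
#' @param v_genes,j_genes optional named vectors (by chain kind) of gene labels
#' @return a `tcr_record`
#' @export
read_structure <- function(path, chain_map = c(A = "alpha", B = "beta"),
                           record_id = NULL, v_genes = NULL, j_genes = NULL) {
  if (!file.exists(path)) stop_with("format_error", paste("no such file:", path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop_with("format_error",
                    paste("unparseable PDB:", conditionMessage(e))))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  chains <- list()
  for (fid in names(chain_map)) {
    kind <- chain_map[[fid]]
    sub <- at[at$chain == fid & at$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop_with("lookup_error", sprintf("chain '%s' not found in %s", fid, path))
    }
    aa <- suppressWarnings(bio3d::aa321(sub$resid))
    aa[is.na(aa) | !(aa %in% AA20)] <- "X"
    icode <- sub$insert
    icode[is.na(icode)] <- ""
    chains[[kind]] <- chain_structure(
      kind,
      data.frame(imgt = sub$resno, icode = icode, aa = aa, atom = sub$elety,
                 x = sub$x, y = sub$y, z = sub$z, stringsAsFactors = FALSE),
      v_gene = if (!is.null(v_genes)) v_genes[[kind]] %||% NA_character_ else NA_character_,
      j_gene = if (!is.null(j_genes)) j_genes[[kind]] %||% NA_character_ else NA_character_)
  }
  kinds <- vapply(chains, `[[`, "", "chain_kind")
  a <- chains[[which(kinds %in% c("alpha", "light"))[1]]]
  b <- chains[[which(kinds %in% c("beta", "heavy"))[1]]]
  if (is.null(a) || is.null(b)) {
    stop_with("usage_error", "chain_map must name an alpha/light and a beta/heavy chain")
  }
  tcr_record(record_id %||% sub("\\.pdb$", "", basename(path)), a, b,
             source = path)
}

#' Write a paired record to PDB
#'
#' Alpha (or light) chain is written as chain A, beta (or heavy) as chain B,
#' with IMGT numbers in the residue-sequence field and insertion codes in the
#' icode field. Coordinates keep PDB precision (3 decimals), so
#' `read_structure(write_structure(x))` round-trips to 1e-3 Angstrom.
#'
#' @param record a `tcr_record`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_structure <- function(record, path) {
  stopifnot(inherits(record, "tcr_record"))
  aa123 <- function(a) {
    out <- suppressWarnings(bio3d::aa123(a))
    out[is.na(out) | out == "X"] <- "UNK"
    out
  }
  ats <- rbind(cbind(record$alpha$atoms, chain = "A"),
               cbind(record$beta$atoms, chain = "B"))
  n <- nrow(ats)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(ats[, c("x", "y", "z")]))),
    resno = ats$imgt,
    resid = aa123(ats$aa),
    insert = ats$icode,
    chain = ats$chain,
    elety = ats$atom,
    eleno = seq_len(n),
    o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Construct a loop structure (one CDR with its anchors)
#'
#' Holds the loop and anchor backbone atoms of one CDR in canonical IMGT
#' order, with precomputed match keys and coordinate matrices for fast
#' pairwise geometry.
#'
#' @param parent_id identifier of the parent record
#' @param chain_kind chain kind of the parent chain
#' @param region_name "CDR1", "CDR2" or "CDR3"
#' @param loop_atoms,anchor_atoms atom data.frames as in [chain_structure()]
#' @param v_gene,j_gene optional gene labels carried along for grouping
#' @return object of class `loop_structure`
#' @export
loop_structure <- function(parent_id, chain_kind, region_name, loop_atoms,
                           anchor_atoms, v_gene = NA_character_,
                           j_gene = NA_character_) {
  region_name <- match.arg(region_name, c("CDR1", "CDR2", "CDR3"))
  def <- region_definitions()[[region_name]]
  fix <- function(df) {
    df$icode <- as.character(df$icode)
    df$icode[is.na(df$icode)] <- ""
    ord <- order(imgt_sort_key(df$imgt, df$icode), match(df$atom, BACKBONE_ATOMS))
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  loop_atoms <- fix(loop_atoms)
  anchor_atoms <- fix(anchor_atoms)
  if (nrow(loop_atoms) == 0) {
    stop_with("empty_region_error",
              sprintf("no residues in %s loop of %s", region_name, parent_id))
  }
  if (!all(loop_atoms$imgt >= min(def$loop) & loop_atoms$imgt <= max(def$loop))) {
    stop_with("integrity_error", "loop residue outside the region's loop range")
  }
  if (nrow(anchor_atoms) > 0 && !all(anchor_atoms$imgt %in% def$anchors)) {
    stop_with("integrity_error", "anchor residue outside the region's anchor set")
  }
  res <- unique(loop_atoms[, c("imgt", "icode")])
  reskey <- paste(loop_atoms$imgt, loop_atoms$icode)
  seq_aa <- loop_atoms$aa[!duplicated(reskey)]
  complete <- all(table(reskey) == 4L) &&
    all(unlist(lapply(split(loop_atoms$atom, reskey),
                      function(a) identical(sort(a), sort(BACKBONE_ATOMS)))))
  structure(list(
    parent_id = parent_id, chain_kind = chain_kind, region_name = region_name,
    loop_atoms = loop_atoms, anchor_atoms = anchor_atoms,
    sequence = paste(seq_aa, collapse = ""),
    n_residues = nrow(res),
    loop_key = paste(loop_atoms$imgt, loop_atoms$icode, loop_atoms$atom),
    anchor_key = paste(anchor_atoms$imgt, anchor_atoms$icode, anchor_atoms$atom),
    loop_xyz = as.matrix(loop_atoms[, c("x", "y", "z")]),
    anchor_xyz = as.matrix(anchor_atoms[, c("x", "y", "z")]),
    complete_backbone = complete,
    anchors_degraded = nrow(anchor_atoms) < 4L * length(def$anchors),
    v_gene = v_gene, j_gene = j_gene), class = "loop_structure")
}

#' @export
print.loop_structure <- function(x, ...) {
  cat(sprintf("<loop_structure %s %s %s: %d res [%s]%s>\n", x$parent_id,
              x$chain_kind, x$region_name, x$n_residues, x$sequence,
              if (x$anchors_degraded) " anchors degraded" else ""))
  invisible(x)
}

#' Extract a CDR loop and its anchors from a record
#'
#' Loop residues are all residues whose IMGT number falls inside the region's
#' loop range (insertion codes included); anchors are the residues at the
#' region's anchor numbers. A region with any absent anchor backbone atom is
#' flagged `anchors_degraded` rather than rejected; downstream superposition
#' uses only atoms present in both partners.
#'
#' @param record a `tcr_record`
#' @param chain_kind which chain ("alpha"/"beta", or "light"/"heavy")
#' @param region_name "CDR1", "CDR2" or "CDR3"
#' @return a `loop_structure`
#' @export
extract_region <- function(record, chain_kind, region_name) {
  stopifnot(inherits(record, "tcr_record"))
  chain <- if (record$alpha$chain_kind == chain_kind) record$alpha
           else if (record$beta$chain_kind == chain_kind) record$beta
           else stop_with("lookup_error",
                          sprintf("record %s has no %s chain", record$record_id, chain_kind))
  def <- region_definitions()[[match.arg(region_name, c("CDR1", "CDR2", "CDR3"))]]
  at <- chain$atoms
  in_loop <- at$imgt >= min(def$loop) & at$imgt <= max(def$loop)
  in_anch <- at$imgt %in% def$anchors
  if (!any(in_loop)) {
    stop_with("empty_region_error",
              sprintf("no residues in %s loop range of %s (%s)", region_name,
                      record$record_id, chain_kind))
  }
  loop_structure(record$record_id, chain_kind, region_name,
                 at[in_loop, , drop = FALSE], at[in_anch, , drop = FALSE],
                 v_gene = chain$v_gene, j_gene = chain$j_gene)
}

#' Extract one region from every record
#'
#' @param records list of `tcr_record`
#' @inheritParams extract_region
#' @return list of `loop_structure`
#' @export
collect_loops <- function(records, chain_kind, region_name) {
  lapply(records, extract_region, chain_kind = chain_kind,
         region_name = region_name)
}

#' Read a V/J gene annotation table
#'
#' CSV with header columns `record_id, alpha_v, alpha_j, beta_v, beta_j`.
#' Empty fields become `NA` (explicit nulls); duplicated record ids are an
#' integrity error.
#'
#' @param path CSV file
#' @return data.frame keyed by `record_id`
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("record_id", "alpha_v", "alpha_j", "beta_v", "beta_j")
  if (!all(need %in% names(tab))) {
    stop_with("format_error",
              paste("gene table must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tab$record_id)) {
    stop_with("integrity_error", sprintf(
      "duplicate record id in gene table: %s",
      tab$record_id[duplicated(tab$record_id)][1]))
  }
  for (cc in need[-1]) tab[[cc]][!nzchar(tab[[cc]]) | is.na(tab[[cc]])] <- NA_character_
  tab[, need]
}
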