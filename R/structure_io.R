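## Reading deposited structures, extracting RNA chains and sanitizing them:
## modified nucleotides are renamed to their parent base, residues with fewer
## than 9 observed heavy atoms are dropped, remaining incomplete residues are
## completed by idealized-residue grafting, and chains shorter than 6
## nucleotides are rejected as unable to form an SSE.

## Curated parent-base lookup for modified nucleotides (from the public
## chemical component dictionary).  Standard codes map to themselves;
## anything absent maps to none.
MODIFIED_PARENT <- c(
  A = "A", C = "C", G = "G", U = "U",
  ## adenosine derivatives
  `1MA` = "A", `2MA` = "A", MA6 = "A", `6MZ` = "A", MIA = "A", T6A = "A",
  RIA = "A", A2M = "A", AP7 = "A", `12A` = "A", `2MZ` = "A", PR5 = "A",
  ## cytidine derivatives
  `5MC` = "C", OMC = "C", `4OC` = "C", M4C = "C", CBV = "C", CCC = "C",
  `10C` = "C", `1SC` = "C", C2L = "C",
  ## guanosine derivatives
  `1MG` = "G", `2MG` = "G", M2G = "G", `7MG` = "G", OMG = "G", YG = "G",
  YYG = "G", QUO = "G", G7M = "G", GTP = "G", GDP = "G", `23G` = "G",
  CG1 = "G", G2L = "G", I = "G",
  ## uridine derivatives
  PSU = "U", `5MU` = "U", H2U = "U", `4SU` = "U", `2MU` = "U", OMU = "U",
  UR3 = "U", RT = "U", `5BU` = "U", DHU = "U", `70U` = "U", `3MU` = "U",
  SSU = "U", U8U = "U", UD5 = "U", MNU = "U"
)

#' Map a residue code to its parent standard base
#'
#' Standard codes map to themselves; modified nucleotides map to their parent
#' base via a curated lookup; anything else (amino acids, DNA residues,
#' water, ligands) maps to `NA`.
#'
#' @param name 3-letter (or shorter) residue code.
#' @return `"A"`, `"C"`, `"G"`, `"U"`, or `NA_character_`.
#' @export
map_modified_residue <- function(name) {
  out <- MODIFIED_PARENT[toupper(trimws(name))]
  out <- unname(out)
  out[is.na(out)] <- NA_character_
  out
}

new_rna_chain <- function(source_id, chain_id, seq, original_names, atoms,
                          ss = NULL, removed_crossing_pairs = NULL) {
  structure(list(source_id = source_id, chain_id = chain_id,
                 seq = seq, original_names = original_names,
                 atoms = atoms, ss = ss,
                 removed_crossing_pairs = removed_crossing_pairs),
            class = "rna_chain")
}

#' @export
print.rna_chain <- function(x, ...) {
  cat(sprintf("<rna_chain %s:%s, %d residues, %d atoms%s>\n",
              x$source_id, x$chain_id, length(x$seq), nrow(x$atoms),
              if (!is.null(x$ss)) ", with secondary structure" else ""))
  invisible(x)
}

chain_length <- function(chain) length(chain$seq)

## atoms of one residue as an atom/elem/x/y/z data.frame
residue_atoms <- function(chain, res) {
  chain$atoms[chain$atoms$res == res, c("atom", "elem", "x", "y", "z"),
              drop = FALSE]
}

chain_xyz <- function(chain) as.matrix(chain$atoms[, c("x", "y", "z")])

#' Read RNA chains from a structure file
#'
#' Reads PDB or mmCIF (detected from the file extension under
#' `format = "auto"`), keeps the first model of multi-model files and the
#' highest-occupancy alternate conformer, and returns one unsanitized
#' [rna_chain] per polymer chain that contains at least one residue mapping
#' to a standard RNA base.  Protein, DNA-only, ligand-only and water chains
#' are excluded.
#'
#' @param path file path.
#' @param format `"auto"`, `"pdb"` or `"cif"`.
#' @return list of `rna_chain` objects (possibly empty).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  obj <- tryCatch(
    if (format == "cif") {
      suppressWarnings(bio3d::read.cif(path))
    } else {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
    },
    error = function(e) stop("cannot parse structure file '", path, "': ",
                             conditionMessage(e)))
  at <- obj$atom
  at$elety <- gsub('"', "", at$elety)
  at$resid <- trimws(at$resid)
  at <- at[is.finite(at$x) & is.finite(at$y) & is.finite(at$z), , drop = FALSE]
  source_id <- toupper(sub("\\.(pdb|cif|ent)$", "",
                           basename(path), ignore.case = TRUE))
  chains <- list()
  for (ch in unique(at$chain)) {
    ca <- at[at$chain %in% ch, , drop = FALSE]
    ## residue identity: resno + insertion code, in file order
    ins <- if ("insert" %in% names(ca)) ifelse(is.na(ca$insert), "", ca$insert)
           else ""
    rid <- paste(ca$resno, ins, sep = "_")
    rid_f <- factor(rid, levels = unique(rid))
    parent_first <- map_modified_residue(
      ca$resid[match(levels(rid_f), rid)])
    if (!any(!is.na(parent_first))) next  # no RNA residue in this chain
    ## altloc: keep highest occupancy per (residue, atom)
    occ <- if ("o" %in% names(ca)) ifelse(is.na(ca$o), 1, ca$o) else 1
    ord <- order(as.integer(rid_f), -occ)
    ca <- ca[ord, , drop = FALSE]
    rid_f <- rid_f[ord]
    dupatom <- duplicated(paste(as.integer(rid_f), ca$elety))
    ca <- ca[!dupatom, , drop = FALSE]
    rid_f <- rid_f[!dupatom]
    nres <- nlevels(rid_f)
    res_index <- as.integer(rid_f)
    names_by_res <- ca$resid[match(seq_len(nres), res_index)]
    atoms <- data.frame(res = res_index,
                        atom = ca$elety,
                        elem = element_of(ca$elety),
                        x = ca$x, y = ca$y, z = ca$z,
                        stringsAsFactors = FALSE)
    chains[[length(chains) + 1]] <- new_rna_chain(
      source_id = source_id,
      chain_id = as.character(ch),
      seq = map_modified_residue(names_by_res),
      original_names = names_by_res,
      atoms = atoms)
  }
  chains
}

#' Sanitize an RNA chain
#'
#' Applies, in order: (1) drop residues with no parent standard base;
#' (2) rename modified residues to the parent base, replacing the base
#' moiety by idealized grafting; (3) drop residues with fewer than 9 observed
#' heavy atoms; (4) complete missing heavy atoms by least-squares grafting of
#' the idealized residue template; (5) reindex residues 1..n; (6) reject the
#' whole chain if fewer than 6 residues remain.
#'
#' @param chain [rna_chain] from [read_structure()].
#' @return list with `chain` (sanitized `rna_chain`, or `NULL` if rejected),
#'   `rejected` (logical) and `report` (data.frame of actions).
#' @export
sanitize_chain <- function(chain) {
  report <- data.frame(action = character(), residue = character(),
                       detail = character(), stringsAsFactors = FALSE)
  note <- function(action, res_label, detail = "") {
    report[nrow(report) + 1, ] <<- c(action, res_label, detail)
  }
  n <- chain_length(chain)
  keep_res <- logical(n)
  res_list <- vector("list", n)
  new_names <- character(n)
  for (r in seq_len(n)) {
    lbl <- paste0(chain$original_names[r], r)
    parent <- chain$seq[r]
    if (is.na(parent)) {
      note("drop_non_nucleotide", lbl)
      next
    }
    at <- residue_atoms(chain, r)
    at <- at[at$elem != "H", , drop = FALSE]
    if (nrow(at) < 9) {
      note("drop_few_atoms", lbl, sprintf("%d atoms", nrow(at)))
      next
    }
    if (chain$original_names[r] != parent) {
      at <- tryCatch(graft_base(at, parent, parent),
                     error = function(e) NULL)
      if (is.null(at)) {
        note("drop_unrenamable", lbl, "incomplete base ring")
        next
      }
      note("rename_modified", lbl, paste("->", parent))
    }
    tpl_atoms <- ideal_nucleotide(parent)$atom
    at <- at[at$atom %in% tpl_atoms, , drop = FALSE]
    if (nrow(at) < 9) {
      note("drop_few_atoms", lbl, sprintf("%d standard atoms", nrow(at)))
      next
    }
    miss <- setdiff(tpl_atoms, at$atom)
    if (length(miss)) {
      at2 <- tryCatch(complete_residue(at, parent), error = function(e) NULL)
      if (is.null(at2)) {
        note("drop_uncompletable", lbl)
        next
      }
      at <- at2
      note("complete_atoms", lbl, paste(miss, collapse = ","))
    } else {
      at <- at[order(match(at$atom, tpl_atoms)), , drop = FALSE]
    }
    keep_res[r] <- TRUE
    res_list[[r]] <- at
    new_names[r] <- parent
  }
  idx <- which(keep_res)
  if (length(idx) < 6) {
    note("reject_chain", sprintf("%s:%s", chain$source_id, chain$chain_id),
         sprintf("%d residues < 6", length(idx)))
    return(list(chain = NULL, rejected = TRUE, report = report))
  }
  atoms <- do.call(rbind, lapply(seq_along(idx), function(k) {
    a <- res_list[[idx[k]]]
    cbind(data.frame(res = k), a)
  }))
  rownames(atoms) <- NULL
  out <- new_rna_chain(chain$source_id, chain$chain_id,
                       seq = new_names[idx],
                       original_names = chain$original_names[idx],
                       atoms = atoms)
  list(chain = out, rejected = FALSE, report = report)
}

#' Deduplicate chains by sequence and secondary structure
#'
#' Chains with identical sequence and identical derived dot-bracket secondary
#' structure keep exactly one representative (the first encountered in input
#' order).  Chains lacking a derived structure get one via
#' [derive_secondary_structure()].
#'
#' @param chains list of sanitized [rna_chain] objects.
#' @param params annotation parameters, see [annotation_params()].
#' @return list of `rna_chain` (each carrying its derived structure).
#' @export
dedupe_chains <- function(chains, params = annotation_params()) {
  if (length(chains) == 0) return(chains)
  chains <- lapply(chains, function(ch) {
    if (is.null(ch$ss)) ch <- derive_secondary_structure(ch, params)
    ch
  })
  key <- vapply(chains, function(ch) {
    paste(paste(ch$seq, collapse = ""), to_dotbracket(ch$ss), sep = "|")
  }, character(1))
  chains[!duplicated(key)]
}

#' Write a chain (or bare atom table) to a PDB file
#'
#' @param chain [rna_chain] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_chain_pdb <- function(chain, path) {
  at <- chain$atoms
  resid <- chain$seq[at$res]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$res, resid = resid, elety = at$atom,
                   chain = rep(substr(chain$chain_id, 1, 1), nrow(at)),
                   elesy = at$elem)
  invisible(path)
}

#' Write a sanitation report as tab-separated text
#'
#' @param report data.frame from [sanitize_chain()].
#' @param path output file path.
#' @export
write_sanitation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
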