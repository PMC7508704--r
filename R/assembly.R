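## Assembly of a 3D model for a target sequence + secondary structure from
## library templates.  The target is decomposed into SSEs, a rank-1 template
## is chosen per SSE, and templates are joined by traversing the stem tree
## from the exterior, superposing each new template onto the already-placed
## model over the anchor atoms (P, C4', C1', N1/N9) of the residues of the
## shared flanking base pairs.  The target sequence is imposed on each
## template by idealized base grafting.

ANCHOR_ATOMS <- c("P", "C4'", "C1'")  # plus the glycosidic nitrogen

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("<assembly_result: %d residues, %d SSE records, energy %.3f>\n",
              length(x$seq), length(x$records),
              if (is.null(x$energy)) NA_real_ else x$energy))
  invisible(x)
}

result_xyz <- function(result) as.matrix(result$atoms[, c("x", "y", "z")])

set_result_xyz <- function(result, xyz) {
  result$atoms$x <- xyz[, 1]
  result$atoms$y <- xyz[, 2]
  result$atoms$z <- xyz[, 3]
  result
}

## atoms of one template residue, renamed to the target base if needed
template_residue_atoms <- function(tpl_atoms, tpl_base, target_base) {
  if (tpl_base == target_base) return(tpl_atoms)
  graft_base(tpl_atoms, tpl_base, target_base)
}

anchor_rows <- function(atoms, residues, bases) {
  sel <- integer(0)
  for (r in residues) {
    want <- c(ANCHOR_ATOMS, GLYCOSIDIC_N[[bases[r]]])
    rows <- which(atoms$res == r & atoms$atom %in% want)
    sel <- c(sel, rows[order(match(atoms$atom[rows], want))])
  }
  sel
}

## residue ownership: stems own their paired residues, loops their unpaired
## segment residues
record_owner <- function(records, n) {
  owner <- integer(n)
  for (k in seq_along(records)) {
    rec <- records[[k]]
    if (rec$sse_type == "stem") owner[rec$residues] <- k
  }
  for (k in seq_along(records)) {
    rec <- records[[k]]
    if (rec$sse_type != "stem") {
      flank_res <- unique(as.vector(rec$flanking_pairs))
      own <- setdiff(rec$residues, flank_res)
      owner[own] <- k
    }
  }
  owner
}

#' Assemble a 3D model from library templates
#'
#' Decomposes the target, retrieves the rank-1 template for every SSE,
#' traverses the stem tree from the exterior and joins each template to the
#' already-placed model by rigid superposition over the shared flanking-pair
#' residues.  The target sequence is imposed on the templates (base moieties
#' grafted where identities differ).  The run is deterministic for a fixed
#' seed.
#'
#' @param sequence target base string.
#' @param ss target secondary structure: [rna_ss()] or a dot-bracket string.
#' @param library a `template_library`.
#' @param exclude_source source accessions excluded from template search
#'   (self-exclusion).
#' @param scheme decomposition scheme; defaults to the library's.
#' @param seed integer seed (recorded; assembly itself is deterministic).
#' @param params [energy_params()] for the initial energy evaluation.
#' @return an `assembly_result`: model atom coordinates, per-SSE template
#'   provenance, restraint topology and initial energy.
#' @export
assemble <- function(sequence, ss, library, exclude_source = character(),
                     scheme = library$scheme, seed = 1,
                     params = energy_params()) {
  if (is.character(ss)) ss <- parse_dotbracket(ss, sequence)
  rc <- remove_crossing_pairs(ss)
  ss <- rc$ss
  bases <- strsplit(ss$sequence, "")[[1]]
  n <- length(bases)
  records <- decompose(ss, scheme)
  chosen <- vector("list", length(records))
  provenance <- vector("list", length(records))
  for (k in seq_along(records)) {
    hits <- search_templates(library, records[[k]], exclude_source,
                             max_hits = 1)
    if (length(hits) == 0)
      stop(sprintf("no template for %s SSE with dot-bracket '%s'",
                   records[[k]]$sse_type, records[[k]]$dot_bracket))
    chosen[[k]] <- hits[[1]]
    provenance[[k]] <- list(sse_type = records[[k]]$sse_type,
                            dot_bracket = records[[k]]$dot_bracket,
                            source_id = hits[[1]]$source_id,
                            source_chain = hits[[1]]$source_chain,
                            identity = attr(hits[[1]], "identity"))
  }
  ## per-record template atoms mapped to target residues, sequence imposed
  tpl_res_atoms <- vector("list", length(records))
  for (k in seq_along(records)) {
    rec <- records[[k]]; tpl <- chosen[[k]]
    tb <- strsplit(gsub("&", "", tpl$sequence), "")[[1]]
    lst <- vector("list", length(rec$residues))
    for (q in seq_along(rec$residues)) {
      pres <- tpl$residues[q]
      at <- tpl$atoms[tpl$atoms$res == pres, c("atom", "elem", "x", "y", "z"),
                      drop = FALSE]
      lst[[q]] <- template_residue_atoms(at, tb[q], bases[rec$residues[q]])
    }
    names(lst) <- as.character(rec$residues)
    tpl_res_atoms[[k]] <- lst
  }
  ## traversal from the exterior
  is_open <- vapply(records, function(r) r$sse_type == "open_loop",
                    logical(1))
  root <- if (any(is_open)) which(is_open)[1] else 1L
  placed_res <- logical(n)
  model <- vector("list", n)
  place_record <- function(k, tr = NULL) {
    lst <- tpl_res_atoms[[k]]
    for (q in seq_along(lst)) {
      r <- records[[k]]$residues[q]
      if (placed_res[r]) next
      at <- lst[[q]]
      if (!is.null(tr)) {
        xyz <- transform_coords(as.matrix(at[, c("x", "y", "z")]), tr)
        at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
      }
      model[[r]] <<- at
      placed_res[r] <<- TRUE
    }
  }
  place_record(root)
  todo <- setdiff(seq_along(records), root)
  while (length(todo)) {
    progressed <- FALSE
    for (k in todo) {
      shared <- records[[k]]$residues[placed_res[records[[k]]$residues]]
      if (length(shared) < 2) next
      ## fixed anchors from the placed model
      fixed <- do.call(rbind, lapply(shared, function(r) {
        at <- model[[r]]
        want <- c(ANCHOR_ATOMS, GLYCOSIDIC_N[[bases[r]]])
        rows <- which(at$atom %in% want)
        cbind(as.matrix(at[rows[order(match(at$atom[rows], want))],
                           c("x", "y", "z")]))
      }))
      moving <- do.call(rbind, lapply(shared, function(r) {
        at <- tpl_res_atoms[[k]][[as.character(r)]]
        want <- c(ANCHOR_ATOMS, GLYCOSIDIC_N[[bases[r]]])
        rows <- which(at$atom %in% want)
        as.matrix(at[rows[order(match(at$atom[rows], want))],
                     c("x", "y", "z")])
      }))
      if (nrow(fixed) != nrow(moving) || nrow(fixed) < 3) next
      tr <- superpose(moving, fixed)
      place_record(k, tr)
      todo <- setdiff(todo, k)
      progressed <- TRUE
      break
    }
    if (!progressed)
      stop("assembly graph is disconnected: cannot place remaining SSEs")
  }
  atoms <- do.call(rbind, lapply(seq_len(n), function(r)
    cbind(data.frame(res = r), model[[r]])))
  rownames(atoms) <- NULL
  owner <- record_owner(records, n)
  result <- structure(list(atoms = atoms, seq = bases, ss = ss,
                           scheme = scheme, records = records,
                           provenance = provenance, owner = owner,
                           seed = seed, energy = NULL, topology = NULL,
                           rmsd_to_reference = NA_real_),
                      class = "assembly_result")
  result$topology <- build_topology(result, params)
  result$energy <- assembly_energy(result, params)
  result
}

#' RMSD of a model against reference coordinates
#'
#' Optimal-superposition RMSD over the selected atoms shared between model
#' and reference, matched by residue index and atom name.
#'
#' @param result `assembly_result`, [rna_chain], or an atom data.frame with
#'   `res`, `atom`, `x`, `y`, `z`.
#' @param reference same accepted types as `result`.
#' @param selection atom names to use, or `"heavy"` for all shared heavy
#'   atoms (default).
#' @return RMSD in angstroms.
#' @export
rmsd_to_reference <- function(result, reference, selection = "heavy") {
  get_atoms <- function(x) {
    if (inherits(x, "assembly_result") || inherits(x, "rna_chain")) x$atoms
    else x
  }
  a <- get_atoms(result); b <- get_atoms(reference)
  if (length(unique(a$res)) != length(unique(b$res)))
    stop("model and reference differ in residue count")
  ka <- paste(a$res, a$atom); kb <- paste(b$res, b$atom)
  shared <- intersect(ka, kb)
  if (!identical(selection, "heavy"))
    shared <- shared[sub("^\\S+ ", "", shared) %in% selection]
  if (length(shared) < 3) stop("fewer than 3 shared atoms in the selection")
  A <- as.matrix(a[match(shared, ka), c("x", "y", "z")])
  B <- as.matrix(b[match(shared, kb), c("x", "y", "z")])
  superpose(A, B)$rmsd
}
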