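# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary data.

# Fixture chain with derived secondary structure attached.
fixture_chain <- function(db, sq = NULL, source_id = "TOYA", chain_id = "A",
                          seed = 1) {
  if (is.null(sq)) {
    set.seed(seed)
    sq <- comp_sequence(db)
  }
  fx <- build_toy_rna(sq, db, seed = seed, source_id = source_id,
                      chain_id = chain_id)
  ch <- derive_secondary_structure(fx$chain)
  stopifnot(to_dotbracket(ch$ss) == db)
  list(chain = ch, raw = fx$chain, ss = fx$ss, sequence = sq, db = db)
}

# Minimal mmCIF text for an rna_chain (single model, single chain).
write_chain_cif <- function(chain, path) {
  at <- chain$atoms
  hdr <- c("data_FIXTURE", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- sprintf(
    'ATOM %d %s "%s" . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s "%s" 1',
    seq_len(nrow(at)), at$elem, at$atom, chain$seq[at$res], chain$chain_id,
    at$res, at$x, at$y, at$z, at$res, chain$seq[at$res], chain$chain_id,
    at$atom)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

# PDB file holding an RNA chain plus a short protein chain B.
write_mixed_pdb <- function(chain, path) {
  write_chain_pdb(chain, path)
  lines <- readLines(path)
  lines <- lines[!grepl("^END", lines)]
  k <- length(lines)
  prot <- sprintf(
    "ATOM  %5d  CA  ALA B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    k + 1:3, 1:3, c(100, 103, 106), c(0, 0, 0), c(0, 0, 0))
  writeLines(c(lines, prot, "END"), path)
  invisible(path)
}
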