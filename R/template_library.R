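## The SSE template library: records grouped by a topology key, exact
## duplicates removed, searchable by topology with sequence-identity
## ranking and a self-exclusion option, persisted as inspectable text
## (per-record PDB fragments plus a line-oriented key-value index).

#' Topology key of an SSE record
#'
#' Two records share a key iff they have the same SSE type and the same
#' dot-bracket pattern (segment lengths and flanking-pair arrangement),
#' ignoring base identity.
#'
#' @param record [sse_record].
#' @return character key.
#' @export
template_key <- function(record) {
  paste(record$sse_type, record$dot_bracket, sep = "|")
}

new_template_library <- function(scheme) {
  structure(list(records = list(), scheme = scheme,
                 provenance = data.frame(source_id = character(),
                                         added = character(),
                                         stringsAsFactors = FALSE),
                 key_index = list()),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library scheme=%s: %d records, %d keys, %d sources>\n",
              x$scheme, length(x$records), length(x$key_index),
              nrow(x$provenance)))
  invisible(x)
}

## exact-duplicate signature: sequence + dot_bracket + coordinates
record_signature <- function(rec) {
  paste(rec$sequence, rec$dot_bracket,
        paste(sprintf("%.3f", as.matrix(rec$atoms[, c("x", "y", "z")])),
              collapse = ","),
        sep = "|")
}

insert_records <- function(lib, records) {
  sigs <- vapply(lib$records, record_signature, character(1))
  for (rec in records) {
    sg <- record_signature(rec)
    if (sg %in% sigs) next
    sigs <- c(sigs, sg)
    lib$records[[length(lib$records) + 1]] <- rec
    key <- template_key(rec)
    lib$key_index[[key]] <- c(lib$key_index[[key]], length(lib$records))
  }
  lib
}

chain_records <- function(chain, scheme) {
  recs <- decompose(chain$ss, scheme)
  recs <- attach_coordinates(chain, recs)
  lapply(recs, function(r) {
    r$atoms[, c("x", "y", "z")] <- round(r$atoms[, c("x", "y", "z")], 3)
    r
  })
}

#' Build an SSE template library from sanitized chains
#'
#' For each chain (processed in deterministic order, sorted by source and
#' chain id): derive the secondary structure if absent, skip pairless
#' chains, decompose under the scheme, attach coordinates and insert the
#' records.  Coordinates are stored at 0.001 A resolution (the precision of
#' the PDB fragment files), and records that duplicate an existing record
#' exactly (sequence, dot-bracket and coordinates) are not inserted twice.
#' Per-chain failures are recorded in the `skipped` attribute, not fatal.
#'
#' @param chains list of sanitized [rna_chain].
#' @param scheme `"lib1"` or `"lib2"`.
#' @param params [annotation_params()] used if a chain has no derived
#'   structure yet.
#' @return a `template_library` object.
#' @export
build_library <- function(chains, scheme = c("lib2", "lib1"),
                          params = annotation_params()) {
  scheme <- match.arg(scheme)
  lib <- new_template_library(scheme)
  if (length(chains) == 0) return(lib)
  ord <- order(vapply(chains, function(ch) ch$source_id, character(1)),
               vapply(chains, function(ch) ch$chain_id, character(1)))
  chains <- chains[ord]
  skipped <- character(0)
  for (ch in chains) {
    if (is.null(ch$ss)) ch <- derive_secondary_structure(ch, params)
    label <- paste(ch$source_id, ch$chain_id, sep = ":")
    if (nrow(ch$ss$pairs) == 0) {
      skipped <- c(skipped, paste(label, "no base pairs"))
      next
    }
    recs <- tryCatch(chain_records(ch, scheme), error = function(e) {
      skipped <<- c(skipped, paste(label, conditionMessage(e)))
      NULL
    })
    if (is.null(recs)) next
    lib <- insert_records(lib, recs)
    if (!(ch$source_id %in% lib$provenance$source_id)) {
      lib$provenance[nrow(lib$provenance) + 1, ] <-
        c(ch$source_id, format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    }
  }
  attr(lib, "skipped") <- skipped
  lib
}

#' Keep one representative per (sequence, dot-bracket)
#'
#' Among records with identical sequence and dot-bracket notation, keeps the
#' one with the lexicographically smallest source id (ties broken by chain
#' id, then insertion order).
#'
#' @param library `template_library`.
#' @return filtered `template_library`.
#' @export
filter_unique <- function(library) {
  if (length(library$records) == 0) return(library)
  key <- vapply(library$records, function(r)
    paste(r$sse_type, r$sequence, r$dot_bracket, sep = "|"), character(1))
  src <- vapply(library$records, function(r)
    paste(r$source_id, r$source_chain, sep = "|"), character(1))
  ord <- order(key, src, seq_along(key))
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)
  out <- new_template_library(library$scheme)
  out$provenance <- library$provenance
  for (k in keep) {
    out$records[[length(out$records) + 1]] <- library$records[[k]]
    ky <- template_key(library$records[[k]])
    out$key_index[[ky]] <- c(out$key_index[[ky]], length(out$records))
  }
  out
}

#' Search the library for templates matching a query SSE
#'
#' Candidates are the records with the same topology key whose source is not
#' excluded, ranked by full-sequence identity over all segments and flanking
#' pairs (descending), then by source id, chain id and insertion order for
#' determinism.
#'
#' @param library `template_library`.
#' @param query [sse_record] (2D is enough: type and dot-bracket pattern).
#' @param exclude_source character vector of source accessions to exclude
#'   (self-exclusion of the target structure).
#' @param max_hits maximum number of records returned.
#' @return list of matching records, each with an `identity` attribute in
#'   `[0, 1]`; may be empty.
#' @export
search_templates <- function(library, query, exclude_source = character(),
                             max_hits = Inf) {
  idx <- library$key_index[[template_key(query)]]
  if (is.null(idx)) return(list())
  cand <- library$records[idx]
  keep <- !vapply(cand, function(r) r$source_id %in% exclude_source,
                  logical(1))
  cand <- cand[keep]
  if (length(cand) == 0) return(list())
  qs <- strsplit(query$sequence, "")[[1]]
  ident <- vapply(cand, function(r) {
    rs <- strsplit(r$sequence, "")[[1]]
    mean(rs == qs)
  }, numeric(1))
  src <- vapply(cand, function(r) r$source_id, character(1))
  chn <- vapply(cand, function(r) r$source_chain, character(1))
  ord <- order(-ident, src, chn, seq_along(cand))
  ord <- ord[seq_len(min(length(ord), max_hits))]
  out <- cand[ord]
  for (k in seq_along(out)) attr(out[[k]], "identity") <- ident[ord[k]]
  out
}

#' Library statistics by loop type
#'
#' Loop records bucketed as in the library summaries: hairpin, bulge,
#' internal, 3wj/4wj/5wj (junctions by incident stem count), nwj (junctions
#' with at least 6 stems), open, plus an `all` row.  `all` counts the raw
#' records, `filter` the records surviving [filter_unique()].
#'
#' @param library `template_library`.
#' @return data.frame with columns `bucket`, `all`, `filter`.
#' @export
library_stats <- function(library) {
  buckets <- c("hairpin", "bulge", "internal", "3wj", "4wj", "5wj", "nwj",
               "open", "all")
  count <- function(lib) {
    v <- stats::setNames(numeric(length(buckets)), buckets)
    for (r in lib$records) {
      b <- switch(r$sse_type,
                  hairpin_loop = "hairpin",
                  bulge_loop = "bulge",
                  internal_loop = "internal",
                  junction = if (r$n_stems >= 6) "nwj"
                             else paste0(r$n_stems, "wj"),
                  open_loop = "open",
                  NA_character_)
      if (is.na(b)) next  # stems are not loops
      v[b] <- v[b] + 1
      v["all"] <- v["all"] + 1
    }
    v
  }
  data.frame(bucket = buckets,
             all = unname(count(library)),
             filter = unname(count(filter_unique(library))))
}

#' Incrementally update a library with new chains
#'
#' Chains whose source accession is already in the provenance are skipped;
#' the result equals rebuilding from the union of the inputs (as a set of
#' records).
#'
#' @param library existing `template_library`.
#' @param new_chains list of sanitized [rna_chain].
#' @param params [annotation_params()].
#' @return updated `template_library`.
#' @export
update_library <- function(library, new_chains,
                           params = annotation_params()) {
  fresh <- Filter(function(ch)
    !(ch$source_id %in% library$provenance$source_id), new_chains)
  if (length(fresh) == 0) return(library)
  add <- build_library(fresh, library$scheme, params)
  lib <- insert_records(library, add$records)
  lib$provenance <- rbind(lib$provenance, add$provenance)
  lib
}

## ---- persistence -----------------------------------------------------

rec_index_block <- function(rec, id) {
  c(sprintf("record %d", id),
    sprintf("type: %s", rec$sse_type),
    sprintf("segments: %s",
            paste(vapply(rec$segments, function(s)
              paste(s[1], s[2], sep = "-"), character(1)), collapse = ",")),
    sprintf("residues: %s", paste(rec$residues, collapse = ",")),
    sprintf("flanking: %s",
            if (nrow(rec$flanking_pairs))
              paste(apply(rec$flanking_pairs, 1, paste, collapse = ":"),
                    collapse = ",")
            else ""),
    sprintf("n_stems: %s",
            if (is.na(rec$n_stems)) "" else rec$n_stems),
    sprintf("sequence: %s", rec$sequence),
    sprintf("dot_bracket: %s", rec$dot_bracket),
    sprintf("length: %d", rec$length),
    sprintf("family: %s", rec$family),
    sprintf("source: %s %s", rec$source_id, rec$source_chain),
    "")
}

#' Save / load a template library
#'
#' On-disk layout: `library.meta` (scheme), `provenance.tsv`, `index.txt`
#' (one line-oriented key-value block per record) and `fragments/` with one
#' PDB file of coordinates per record.  The round trip reproduces records,
#' keys and provenance exactly (coordinates are stored at the 0.001 A
#' resolution they already carry).
#'
#' @param library `template_library`.
#' @param dir directory to create/populate.
#' @return `save_library` the directory, `load_library` a
#'   `template_library`.
#' @export
save_library <- function(library, dir) {
  dir.create(file.path(dir, "fragments"), recursive = TRUE,
             showWarnings = FALSE)
  writeLines(c(sprintf("scheme: %s", library$scheme),
               sprintf("records: %d", length(library$records))),
             file.path(dir, "library.meta"))
  utils::write.table(library$provenance, file.path(dir, "provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- unlist(lapply(seq_along(library$records), function(k)
    rec_index_block(library$records[[k]], k)))
  writeLines(if (is.null(idx)) character(0) else idx,
             file.path(dir, "index.txt"))
  for (k in seq_along(library$records)) {
    rec <- library$records[[k]]
    at <- rec$atoms
    bases <- strsplit(gsub("&", "", rec$sequence), "")[[1]]
    resid <- bases[match(at$res, rec$residues)]
    bio3d::write.pdb(file = file.path(dir, "fragments",
                                      sprintf("rec%05d.pdb", k)),
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$res, resid = resid, elety = at$atom,
                     chain = rep("A", nrow(at)), elesy = at$elem)
  }
  invisible(dir)
}

#' @rdname save_library
#' @export
load_library <- function(dir) {
  meta <- readLines(file.path(dir, "library.meta"))
  scheme <- sub("^scheme: ", "", meta[1])
  lib <- new_template_library(scheme)
  lib$provenance <- utils::read.table(file.path(dir, "provenance.tsv"),
                                      header = TRUE, sep = "\t",
                                      colClasses = "character")
  lines <- readLines(file.path(dir, "index.txt"))
  starts <- grep("^record ", lines)
  val <- function(block, key) {
    ln <- grep(paste0("^", key, ": "), block, value = TRUE)[1]
    if (is.na(ln)) "" else sub(paste0("^", key, ": ?"), "", ln)
  }
  for (b in seq_along(starts)) {
    from <- starts[b]
    to <- if (b < length(starts)) starts[b + 1] - 1 else length(lines)
    block <- lines[from:to]
    id <- as.integer(sub("^record ", "", lines[from]))
    pdb <- suppressWarnings(
      bio3d::read.pdb(file.path(dir, "fragments",
                                sprintf("rec%05d.pdb", id))))
    at <- pdb$atom
    atoms <- data.frame(res = at$resno, atom = at$elety,
                        elem = element_of(at$elety),
                        x = at$x, y = at$y, z = at$z,
                        stringsAsFactors = FALSE)
    segs <- strsplit(val(block, "segments"), ",")[[1]]
    segments <- lapply(strsplit(segs, "-"), function(v)
      as.integer(v))
    fl <- val(block, "flanking")
    flanking <- if (nzchar(fl)) {
      do.call(rbind, lapply(strsplit(strsplit(fl, ",")[[1]], ":"),
                            function(v) as.integer(v)))
    } else matrix(integer(), 0, 2)
    src <- strsplit(val(block, "source"), " ")[[1]]
    ns <- val(block, "n_stems")
    rec <- structure(list(
      sse_type = val(block, "type"),
      segments = segments,
      flanking_pairs = flanking,
      residues = as.integer(strsplit(val(block, "residues"), ",")[[1]]),
      n_stems = if (nzchar(ns)) as.integer(ns) else NA_integer_,
      sequence = val(block, "sequence"),
      dot_bracket = val(block, "dot_bracket"),
      length = as.integer(val(block, "length")),
      family = val(block, "family"),
      source_id = if (length(src) >= 1) src[1] else "",
      source_chain = if (length(src) >= 2) src[2] else "",
      atoms = atoms), class = "sse_record")
    lib$records[[length(lib$records) + 1]] <- rec
    key <- template_key(rec)
    lib$key_index[[key]] <- c(lib$key_index[[key]], length(lib$records))
  }
  lib
}
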