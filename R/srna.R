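#' Antisense sRNA design
#'
#' Sequence-level design of synthetic antisense small RNAs: a
#' target-binding residue complementary to the translation-initiation
#' region of the target mRNA, fused to an sRNA scaffold (MicC, DsrA or
#' MicF type) and a transcription terminator. Coordinates follow
#' biological numbering with no position zero: the A of the start codon
#' is +1 and -1 is the nucleotide immediately upstream. The default
#' window, +1..+24, yields a 24-nt binding sequence spanning the start
#' codon and the first seven downstream codons.
#'
#' The bundled scaffold and terminator sequences are constructed
#' stand-ins (hairpin-plus-U-tract architecture), labelled synthetic in
#' their file names and headers; supply your own FASTA to use the natural
#' sequences.
#'
#' @name srna-design
NULL

normalize_seq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L)
    stop(what, " must be a single character string")
  s <- toupper(gsub("[[:space:]]", "", x))
  s <- chartr("U", "T", s)
  if (nzchar(s) && grepl("[^ACGT]", s))
    stop(what, " contains characters other than A, C, G, T, U")
  s
}

#' Reverse complement of a DNA sequence
#'
#' U is normalised to T on input. Applying the operation twice returns
#' the original (normalised) sequence.
#'
#' @param x a single DNA/RNA sequence string.
#' @return the reverse-complement string.
#' @export
reverse_complement <- function(x) {
  s <- normalize_seq(x)
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Define a target window in start-codon coordinates
#'
#' Offsets are relative to the A of the start codon (+1); there is no
#' position 0, so -1 abuts +1 and a window crossing the boundary is one
#' shorter than the naive difference suggests: -4..+48 spans 52
#' nucleotides.
#'
#' @param start_offset,end_offset integer offsets, non-zero,
#'   `end_offset >= start_offset`.
#' @return a list of class `"target_window"` with a `length` field.
#' @export
target_window <- function(start_offset = 1L, end_offset = 24L) {
  if (start_offset == 0L || end_offset == 0L)
    stop("there is no position 0 in start-codon coordinates")
  if (end_offset < start_offset)
    stop("end_offset must be >= start_offset")
  crosses <- start_offset < 0 && end_offset > 0
  len <- end_offset - start_offset + 1L - as.integer(crosses)
  if (len < 1L) stop("window length must be >= 1")
  structure(list(start_offset = as.integer(start_offset),
                 end_offset = as.integer(end_offset),
                 length = as.integer(len)),
            class = "target_window")
}

#' @export
print.target_window <- function(x, ...) {
  cat("Target window ", x$start_offset, "..", x$end_offset, " (",
      x$length, " nt, A of start codon = +1)\n", sep = "")
  invisible(x)
}

#' Design an antisense binding sequence
#'
#' Extracts the sense-strand window around the start codon and returns
#' its reverse complement — the 5' binding residue of the antisense sRNA.
#' The default window +1..+24 yields a 24-nt binding sequence.
#'
#' @param cds_with_context the sense-strand sequence containing the start
#'   codon, optionally with 5' context (needed for negative offsets).
#' @param start_index 1-based position of the A of the start codon within
#'   `cds_with_context`.
#' @param window a [target_window()] (default +1..+24).
#' @return the antisense binding sequence (character), with attributes
#'   `window` and `sense_window` (the extracted sense-strand segment).
#'   A start codon other than ATG (GTG/TTG starts exist) triggers a
#'   warning, not an error.
#' @export
design_binding_sequence <- function(cds_with_context, start_index,
                                    window = target_window(1L, 24L)) {
  s <- normalize_seq(cds_with_context, "cds_with_context")
  stopifnot(inherits(window, "target_window"))
  if (start_index < 1L || start_index + 2L > nchar(s))
    stop("start_index outside the supplied sequence")
  codon <- substr(s, start_index, start_index + 2L)
  if (codon != "ATG")
    warning("codon at start_index is ", codon,
            ", not ATG (GTG/TTG starts exist)")
  to_index <- function(o) if (o > 0) start_index + o - 1L else
    start_index + o
  i1 <- to_index(window$start_offset)
  i2 <- to_index(window$end_offset)
  if (i1 < 1L || i2 > nchar(s))
    stop("window ", window$start_offset, "..", window$end_offset,
         " falls outside the supplied sequence (needs indices ", i1,
         "..", i2, ")")
  sense <- substr(s, i1, i2)
  out <- reverse_complement(sense)
  attr(out, "window") <- window
  attr(out, "sense_window") <- sense
  out
}

scaffold_file <- function()
  system.file("extdata", "srna_scaffolds_synthetic.fasta",
              package = "cgflux", mustWork = TRUE)

terminator_file <- function()
  system.file("extdata", "srna_terminators_synthetic.fasta",
              package = "cgflux", mustWork = TRUE)

read_fasta_first <- function(path, name = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (is.null(name)) return(list(id = ids[1],
                                 seq = as.character(set[[1]])))
  hit <- match(name, ids)
  if (is.na(hit)) stop("no sequence named '", name, "' in ", path,
                       " (available: ", paste(ids, collapse = ", "), ")")
  list(id = ids[hit], seq = as.character(set[[hit]]))
}

#' Assemble an antisense sRNA cassette
#'
#' Concatenates binding residue, scaffold and terminator, in that order.
#'
#' @param binding the antisense binding sequence (non-empty).
#' @param scaffold_name `"MicC"`, `"DsrA"`, `"MicF"` (bundled synthetic
#'   stand-ins) or `"custom"` (requires `scaffold_fasta`).
#' @param scaffold_fasta optional FASTA overriding the bundled scaffold;
#'   with `scaffold_name = "custom"` the first record is used, otherwise
#'   the record matching `scaffold_name`.
#' @param terminator_fasta optional FASTA with the terminator (first
#'   record); defaults to the bundled synthetic terminator.
#' @param target_id optional label of the target gene.
#' @return a list of class `"srna_design"` with fields `target_id`,
#'   `binding_sequence`, `scaffold_name`, `scaffold_sequence`,
#'   `terminator_sequence`, `full_sequence` and `provenance`.
#' @export
assemble_srna <- function(binding, scaffold_name = c("MicC", "DsrA",
                                                     "MicF", "custom"),
                          scaffold_fasta = NULL, terminator_fasta = NULL,
                          target_id = NA_character_) {
  scaffold_name <- match.arg(scaffold_name)
  binding <- normalize_seq(as.character(binding), "binding sequence")
  if (!nzchar(binding)) stop("binding sequence must be non-empty")
  if (scaffold_name == "custom") {
    if (is.null(scaffold_fasta))
      stop("scaffold_name 'custom' requires a scaffold_fasta file")
    sc <- read_fasta_first(scaffold_fasta)
    sc_prov <- scaffold_fasta
  } else if (!is.null(scaffold_fasta)) {
    sc <- read_fasta_first(scaffold_fasta, scaffold_name)
    sc_prov <- scaffold_fasta
  } else {
    sc <- read_fasta_first(scaffold_file(), scaffold_name)
    sc_prov <- "bundled synthetic stand-in"
  }
  if (!is.null(terminator_fasta)) {
    tm <- read_fasta_first(terminator_fasta)
    tm_prov <- terminator_fasta
  } else {
    tm <- read_fasta_first(terminator_file())
    tm_prov <- "bundled synthetic stand-in"
  }
  scaffold_seq <- normalize_seq(sc$seq, "scaffold sequence")
  terminator_seq <- normalize_seq(tm$seq, "terminator sequence")
  structure(list(target_id = target_id,
                 binding_sequence = binding,
                 scaffold_name = scaffold_name,
                 scaffold_sequence = scaffold_seq,
                 terminator_sequence = terminator_seq,
                 full_sequence = paste0(binding, scaffold_seq,
                                        terminator_seq),
                 provenance = list(scaffold = sc_prov,
                                   terminator = tm_prov)),
            class = "srna_design")
}

#' @export
print.srna_design <- function(x, ...) {
  cat("Antisense sRNA design",
      if (!is.na(x$target_id)) paste0(" for ", x$target_id), ":\n",
      sep = "")
  cat("  binding   (", nchar(x$binding_sequence), " nt): ",
      x$binding_sequence, "\n", sep = "")
  cat("  scaffold  (", nchar(x$scaffold_sequence), " nt, ",
      x$scaffold_name, ", ", x$provenance$scaffold, ")\n", sep = "")
  cat("  terminator(", nchar(x$terminator_sequence), " nt)\n", sep = "")
  cat("  full      (", nchar(x$full_sequence), " nt)\n", sep = "")
  invisible(x)
}

#' Write an sRNA design as FASTA
#'
#' @param design an [assemble_srna()] result.
#' @param path output FASTA file.
#' @return invisibly `path`.
#' @export
write_srna_fasta <- function(design, path) {
  id <- if (is.na(design$target_id)) "srna_design" else
    paste0("anti-", design$target_id)
  set <- Biostrings::DNAStringSet(design$full_sequence)
  names(set) <- paste0(id, " binding=", nchar(design$binding_sequence),
                       "nt scaffold=", design$scaffold_name)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write an sRNA design report as TSV
#'
#' @param designs a single `srna_design` or a list of them.
#' @param path output TSV file.
#' @return invisibly `path`.
#' @export
write_srna_report_tsv <- function(designs, path) {
  if (inherits(designs, "srna_design")) designs <- list(designs)
  df <- do.call(rbind, lapply(designs, function(d)
    data.frame(target_id = d$target_id,
               binding_sequence = d$binding_sequence,
               binding_length = nchar(d$binding_sequence),
               scaffold_name = d$scaffold_name,
               scaffold_length = nchar(d$scaffold_sequence),
               terminator_length = nchar(d$terminator_sequence),
               full_length = nchar(d$full_sequence),
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
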