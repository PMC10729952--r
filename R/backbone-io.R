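#' Backbone structure container
#'
#' A `backbone` object holds the per-residue backbone heavy atoms of one
#' protein chain: N, C-alpha, C and O coordinates, a presence mask, and an
#' optional native sequence.  Internal residue indexing is 0-based-free,
#' dense and contiguous (1..L in R); author residue identifiers are kept
#' only for reporting.
#'
#' @param n,ca,c,o L x 3 numeric matrices of Angstrom coordinates.
#' @param mask logical vector of length L; `TRUE` means all four atoms are
#'   present.  Coordinates at masked positions may be `NA`.
#' @param native_seq optional one-letter sequence string of length L
#'   (`'X'` allowed), or `NULL`.
#' @param chain_id chain identifier (single string).
#' @param residue_ids character vector of author residue ids (number plus
#'   insertion code), length L.
#' @return An object of class `backbone`.
#' @export
backbone <- function(n, ca, c, o, mask = NULL, native_seq = NULL,
                     chain_id = "A", residue_ids = NULL) {
  n <- as_coord_matrix(n); ca <- as_coord_matrix(ca)
  c <- as_coord_matrix(c); o <- as_coord_matrix(o)
  L <- nrow(ca)
  if (L < 1L) stop("backbone must contain at least one residue")
  if (nrow(n) != L || nrow(c) != L || nrow(o) != L)
    stop("coordinate matrices must have identical row counts")
  if (is.null(mask)) {
    mask <- stats::complete.cases(cbind(n, ca, c, o))
  }
  mask <- as.logical(mask)
  if (length(mask) != L) stop("mask length must equal residue count")
  for (m in list(n, ca, c, o)) {
    if (any(!is.finite(m[mask, , drop = FALSE])))
      stop("non-finite coordinates at unmasked positions")
  }
  if (!is.null(native_seq)) {
    sq <- if (length(native_seq) == 1L) strsplit(native_seq, "")[[1L]] else native_seq
    if (length(sq) != L) stop("native sequence length must equal residue count")
    native_seq <- paste(sq, collapse = "")
  }
  if (is.null(residue_ids)) residue_ids <- as.character(seq_len(L))
  structure(list(length = L, n = n, ca = ca, c = c, o = o,
                 mask = mask, native_seq = native_seq,
                 chain_id = chain_id, residue_ids = as.character(residue_ids)),
            class = "backbone")
}

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must be L x 3")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> chain %s, %d residues (%d unmasked)%s\n",
              x$chain_id, x$length, sum(x$mask),
              if (is.null(x$native_seq)) "" else ", with native sequence"))
  invisible(x)
}

#' Read a backbone chain from a PDB or mmCIF file
#'
#' Parses one polymer chain and extracts the N/CA/C/O backbone atoms per
#' residue in author order.  Alternate locations are resolved to the highest
#' occupancy (ties broken lexicographically by altloc code); residues
#' missing any of the four backbone atoms are masked; selenomethionine (MSE)
#' is read as methionine and other non-standard residues as `'X'`.  Only the
#' first model of multi-model files is used.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param chain chain identifier to extract; if `NULL` and the file holds a
#'   single chain, that chain is used.
#' @return A [backbone] object with `native_seq` taken from the residue
#'   names in the file.
#' @export
read_backbone <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stop("unreadable structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  # first model only: bio3d returns first model for multi=FALSE; cif readers
  # may include all - keep atoms of the first model if a model column exists
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  # keep amino-acid residues only (standard 20 + MSE); drop waters/ligands
  at <- at[at$resid %in% names(AA_THREE_TO_ONE) |
             (at$type == "ATOM" & at$elety %in% c("N", "CA", "C", "O")),
           , drop = FALSE]
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) != 1L)
      stop("file has chains {", paste(chains, collapse = ","),
           "}; specify one")
    chain <- chains
  }
  if (!chain %in% chains)
    stop("chain '", chain, "' not present; available chains: {",
         paste(sort(chains), collapse = ","), "}")
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' has no atoms")

  # altloc resolution: highest occupancy, then lexicographic altloc code
  at$..row <- seq_len(nrow(at))
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  key <- paste(at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$..row), , drop = FALSE]   # restore file order

  rkey <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert), sep = "\r")
  res_ids <- unique(rkey)
  L <- length(res_ids)
  mk_mat <- function() matrix(NA_real_, L, 3)
  cN <- mk_mat(); cCA <- mk_mat(); cC <- mk_mat(); cO <- mk_mat()
  seq_chr <- character(L)
  for (i in seq_len(L)) {
    rows <- at[rkey == res_ids[i], , drop = FALSE]
    res3 <- rows$resid[1L]
    seq_chr[i] <- if (res3 %in% names(AA_THREE_TO_ONE)) AA_THREE_TO_ONE[[res3]] else "X"
    for (el in c("N", "CA", "C", "O")) {
      r <- rows[rows$elety == el, , drop = FALSE]
      if (nrow(r) >= 1L) {
        xyz <- c(r$x[1L], r$y[1L], r$z[1L])
        switch(el,
               N = { cN[i, ] <- xyz }, CA = { cCA[i, ] <- xyz },
               C = { cC[i, ] <- xyz }, O = { cO[i, ] <- xyz })
      }
    }
  }
  mask <- stats::complete.cases(cbind(cN, cCA, cC, cO))
  backbone(cN, cCA, cC, cO, mask = mask, native_seq = seq_chr,
           chain_id = chain, residue_ids = trimws(gsub("\r", "", res_ids)))
}

#' Write a backbone to PDB text
#'
#' Emits standard ATOM records (N, CA, C, O per residue; masked residues'
#' missing atoms are skipped, present atoms written).  Coordinates are
#' rounded to the 3-decimal PDB precision.
#'
#' @param x a [backbone] object.
#' @param path output file path.
#' @param seq optional sequence to write as residue names (defaults to the
#'   structure's native sequence, else poly-glycine).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, seq = NULL) {
  stopifnot(inherits(x, "backbone"))
  if (is.null(seq)) seq <- x$native_seq
  if (is.null(seq)) seq <- paste(rep("G", x$length), collapse = "")
  sq <- strsplit(seq, "")[[1L]]
  one_to_three <- stats::setNames(names(AA_THREE_TO_ONE)[1:20], AA_THREE_TO_ONE[1:20])
  lines <- character(0)
  serial <- 0L
  atoms <- list(N = x$n, CA = x$ca, C = x$c, O = x$o)
  for (i in seq_len(x$length)) {
    res3 <- if (!is.na(sq[i]) && sq[i] %in% names(one_to_three)) one_to_three[[sq[i]]] else "UNK"
    for (el in names(atoms)) {
      xyz <- atoms[[el]][i, ]
      if (any(!is.finite(xyz))) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", el), res3, substr(x$chain_id, 1, 1), i,
        xyz[1], xyz[2], xyz[3], 1.0, 0.0, substr(el, 1, 1)))
    }
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

#' Design record
#'
#' Per-structure design output: the per-residue categorical distribution
#' over the 20 amino acids plus one or more sampled sequences.
#'
#' @param id structure identifier.
#' @param probs L x 20 matrix of per-residue probabilities (rows sum to 1;
#'   masked rows may be `NA`).
#' @param sequences character vector of sampled sequences (each length L).
#' @param temperature sampling temperature used.
#' @param seed sampling seed used.
#' @return An object of class `design_record`.
#' @export
design_record <- function(id, probs, sequences, temperature = 0, seed = NA_integer_) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 20L) stop("probs must have 20 columns")
  ok <- stats::complete.cases(probs)
  if (any(ok)) {
    s <- rowSums(probs[ok, , drop = FALSE])
    if (any(abs(s - 1) > 1e-6)) stop("probability rows must sum to 1")
  }
  for (sq in sequences)
    if (nchar(sq) != nrow(probs)) stop("sequence length must equal L")
  structure(list(id = id, probs = probs, sequences = as.character(sequences),
                 temperature = temperature, seed = seed),
            class = "design_record")
}

#' Write design records to FASTA
#'
#' One FASTA entry per sampled sequence; headers carry the structure id,
#' sample index, temperature and seed; sequences are wrapped at 60 columns.
#'
#' @param records non-empty list of [design_record] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "design_record")) records <- list(records)
  if (length(records) == 0L) stop("records must be non-empty")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  for (rec in records) {
    for (k in seq_along(rec$sequences)) {
      writeLines(sprintf(">%s|sample=%d|T=%g|seed=%s",
                         rec$id, k, rec$temperature, rec$seed), con)
      sq <- rec$sequences[[k]]
      starts <- seq(1L, nchar(sq), by = 60L)
      writeLines(substring(sq, starts, pmin(starts + 59L, nchar(sq))), con)
    }
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Minimal FASTA reader used by the evaluation command line.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  idx <- cumsum(hdr)
  names_ <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  stats::setNames(toupper(gsub("\\s", "", seqs)), names_)
}
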