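# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary fixtures.

# a small mixed-secondary-structure backbone, deterministic under seed
fixture_backbone <- function(seed = 3L, lengths = c(10, 12, 8)) {
  bb <- make_backbone(synthetic_spec(
    data.frame(type = c("helix", "coil", "strand"), length = lengths),
    seed = seed))
  bb$native_seq <- label_sequence(bb)
  bb
}

# a random "coil only" backbone of length L (diverse local geometry)
fixture_coil <- function(L = 20L, seed = 7L) {
  make_backbone(synthetic_spec(data.frame(type = "coil", length = L),
                               seed = seed))
}

# text of a 3-residue PDB file with all backbone atoms present
fixture_pdb_text <- function() {
  bb <- fixture_backbone(seed = 11L, lengths = c(2, 1, 1))
  tf <- tempfile(fileext = ".pdb")
  write_pdb(bb, tf, seq = "ACD")
  on.exit(unlink(tf))
  # keep only the first 3 residues' records
  lines <- readLines(tf)
  keep <- grepl("^ATOM", lines) &
    as.integer(substr(lines, 23, 26)) <= 3
  c(lines[keep], "TER", "END")
}

write_fixture_pdb <- function(lines = fixture_pdb_text()) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}

# brute-force O(L^2) contact edges on virtual C-beta coordinates
brute_edges <- function(bb, cutoff) {
  cb <- virtual_cbeta(bb)
  idx <- which(bb$mask)
  src <- integer(0); dst <- integer(0)
  for (i in idx) for (j in idx) {
    if (i == j) next
    if (sqrt(sum((cb[i, ] - cb[j, ])^2)) <= cutoff) {
      src <- c(src, j); dst <- c(dst, i)
    }
  }
  cbind(src = src, dst = dst)
}

edge_set_string <- function(src, dst) sort(paste(src, dst))
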