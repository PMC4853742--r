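#' Read ion-position frames from a text file
#'
#' Accepts either whitespace-separated `x y z` per ion per line with frames
#' separated by blank lines, or PDB-style input where each `MODEL` block is
#' a frame and ion positions are taken from ATOM/HETATM records.
#'
#' @param path Input file path.
#' @return List of n x 3 numeric matrices (Angstrom), one per frame.
#' @export
read_ion_frames <- function(path) {
  lines <- readLines(path)
  if (any(startsWith(lines, "MODEL"))) {
    starts <- which(startsWith(lines, "MODEL"))
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(starts) != length(ends)) {
      stop("unbalanced MODEL/ENDMDL records in ", path)
    }
    return(lapply(seq_along(starts), function(i) {
      block <- lines[starts[i]:ends[i]]
      at <- block[startsWith(block, "ATOM") | startsWith(block, "HETATM")]
      if (length(at) == 0) return(matrix(numeric(0), ncol = 3))
      cbind(as.numeric(substr(at, 31, 38)),
            as.numeric(substr(at, 39, 46)),
            as.numeric(substr(at, 47, 54)))
    }))
  }
  lines <- trimws(lines)
  lines <- lines[!startsWith(lines, "#")]
  grp <- cumsum(lines == "")
  frames <- split(lines[lines != ""], grp[lines != ""])
  unname(lapply(frames, function(fl) {
    vals <- lapply(strsplit(fl, "\\s+"), as.numeric)
    bad <- vapply(vals, function(v) length(v) != 3 || anyNA(v), logical(1))
    if (any(bad)) {
      stop("malformed ion frame line: ", fl[which(bad)[1]])
    }
    do.call(rbind, vals)
  }))
}

# one-letter to three-letter residue codes
.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Convert a one-letter peptide string to three-letter residue codes
#' @param x Character string of one-letter amino-acid codes.
#' @return Character vector of three-letter codes.
#' @export
peptide_to_codes <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  letters1 <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(letters1, names(.AA1TO3))
  if (length(bad) > 0) {
    stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  unname(.AA1TO3[letters1])
}

#' Simulate a measurement stream for a residue sequence
#'
#' Draws M i.i.d. currents per residue from each residue's distribution
#' and concatenates them in sequence order.
#'
#' @param sequence Character vector of residue codes (names of `dists`).
#' @param dists Named list of `current_distribution` objects.
#' @param M Measurements per residue.
#' @param seed Integer seed.
#' @return Numeric vector of length `length(sequence) * M` (nA).
#' @export
simulate_stream <- function(sequence, dists, M, seed = 1L) {
  dists <- .check_dists(dists)
  missing <- setdiff(sequence, names(dists))
  if (length(missing) > 0) {
    stop("no distribution for residue(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(M >= 1)
  .with_seed(seed, {
    unlist(lapply(sequence, function(res) dist_sample(dists[[res]], M)))
  })
}
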