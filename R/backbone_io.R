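# Backbone structures: construction, PDB input/output, synthetic fixtures.

# Ideal backbone geometry (averages over high-resolution structures).
.BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231)
.ANGLE <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7, CA_C_O = 120.5)

#' Construct a backbone Structure
#'
#' A `Structure` holds ordered backbone coordinates (N, CA, C, O per
#' residue), the residue sequence, and chain topology. Residues are indexed
#' 1..L sequentially over the concatenated chains in file order; original
#' PDB numbering is retained as metadata only.
#'
#' @param coords numeric array `L x 4 x 3` of Angstrom positions, atom order
#'   N, CA, C, O.
#' @param sequence character scalar of length-L over [AA_ALPHABET].
#' @param chain_id character vector of length L; runs must be contiguous.
#' @param resno optional integer vector of original residue numbers.
#' @return object of class `Structure` with fields `n`, `coords`,
#'   `sequence`, `chain_id`, `chains` (data.frame chain/start/end, 1-based
#'   inclusive), and `breaks` (indices i with a CA-CA gap > 4.5 A to i+1
#'   inside one chain; treated as virtual chain ends for dihedrals).
#' @export
structure_new <- function(coords, sequence, chain_id = NULL, resno = NULL) {
  L <- dim(coords)[1]
  stopifnot(L >= 1, length(dim(coords)) == 3, dim(coords)[2] == 4, dim(coords)[3] == 3)
  if (nchar(sequence) != L) stop("sequence length != number of residues")
  seq_to_int(sequence)  # validates alphabet
  if (is.null(chain_id)) chain_id <- rep("A", L)
  if (length(chain_id) != L) stop("chain_id length mismatch")
  if (is.null(resno)) resno <- seq_len(L)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  r <- rle(chain_id)
  if (anyDuplicated(r$values)) stop("chain ids are not contiguous")
  end <- cumsum(r$lengths)
  chains <- data.frame(chain = r$values, start = c(1L, head(end, -1L) + 1L),
                       end = end, stringsAsFactors = FALSE)
  dimnames(coords) <- list(NULL, c("N", "CA", "C", "O"), c("x", "y", "z"))
  x <- list(n = L, coords = coords, sequence = sequence, chain_id = chain_id,
            resno = as.integer(resno), chains = chains)
  x$breaks <- .find_chain_breaks(coords, chain_id)
  class(x) <- "Structure"
  x
}

.find_chain_breaks <- function(coords, chain_id) {
  L <- dim(coords)[1]
  if (L < 2) return(integer(0))
  ca <- coords[, "CA", , drop = FALSE]
  d <- sqrt(rowSums((ca[-1, 1, , drop = FALSE] - ca[-L, 1, , drop = FALSE])^2))
  which(d > 4.5 & chain_id[-L] == chain_id[-1])
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d residues, %d chain(s) [%s]\n", x$n,
              nrow(x$chains), paste(x$chains$chain, collapse = ",")))
  cat("sequence:", x$sequence, "\n")
  invisible(x)
}

#' Extract CA coordinates
#' @param structure a [structure_new()] Structure.
#' @return `L x 3` matrix.
#' @export
ca_coords <- function(structure) {
  structure$coords[, "CA", , drop = TRUE]
}

#' Read a backbone Structure from PDB text
#'
#' Parses ATOM records (plus HETATM for MSE/SEC) of the first model,
#' keeping the N, CA, C and O atoms. Alternate locations are resolved to
#' the highest occupancy; MSE maps to M and SEC to C, other nonstandard
#' residues are dropped with a warning.
#'
#' @param pdb_text character scalar or vector of PDB lines, or a file path.
#' @param policy `"reject"` errors on a residue missing any backbone atom;
#'   `"drop_incomplete"` drops such residues.
#' @return a `Structure`.
#' @export
read_backbone <- function(pdb_text, policy = c("reject", "drop_incomplete")) {
  policy <- match.arg(policy)
  lines <- if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
               file.exists(pdb_text)) {
    readLines(pdb_text)
  } else if (length(pdb_text) == 1L) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    pdb_text
  }
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]  # first model only
  rec <- substr(lines, 1, 6)
  keep <- grepl("^ATOM", rec) | (grepl("^HETATM", rec) &
            trimws(substr(lines, 18, 20)) %in% c("MSE", "SEC"))
  lines <- lines[keep]
  if (!length(lines)) stop("no protein residues found in PDB input")
  atom <- trimws(substr(lines, 13, 16))
  alt <- substr(lines, 17, 17)
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  resno <- as.integer(substr(lines, 23, 26))
  icode <- substr(lines, 27, 27)
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  sel <- atom %in% c("N", "CA", "C", "O")
  if (!any(sel)) stop("no backbone atoms found in PDB input")
  df <- data.frame(atom = atom, alt = alt, resname = resname, chain = chain,
                   resno = resno, icode = icode, x = x, y = y, z = z,
                   occ = occ, stringsAsFactors = FALSE)[sel, ]
  # residue key in file order
  key <- paste(df$chain, df$resno, df$icode, sep = "|")
  df$key <- factor(key, levels = unique(key))
  res_list <- split(df, df$key)
  L0 <- length(res_list)
  coords <- array(NA_real_, c(L0, 4, 3))
  atoms <- c("N", "CA", "C", "O")
  seq1 <- character(L0)
  ch <- character(L0)
  rn <- integer(L0)
  ok <- logical(L0)
  dropped_nonstd <- character(0)
  for (i in seq_len(L0)) {
    r <- res_list[[i]]
    one <- AA_THREE_TO_ONE[r$resname[1]]
    if (is.na(one)) {
      dropped_nonstd <- c(dropped_nonstd, r$resname[1])
      next
    }
    complete <- TRUE
    for (a in seq_along(atoms)) {
      ra <- r[r$atom == atoms[a], , drop = FALSE]
      if (!nrow(ra)) { complete <- FALSE; break }
      ra <- ra[which.max(ra$occ), ]  # altloc: highest occupancy
      coords[i, a, ] <- c(ra$x, ra$y, ra$z)
    }
    if (!complete) {
      if (policy == "reject") {
        stop(sprintf("residue %s%d (chain %s) is missing backbone atom %s",
                     r$resname[1], r$resno[1], r$chain[1], atoms[a]))
      }
      next
    }
    seq1[i] <- one
    ch[i] <- r$chain[1]
    rn[i] <- r$resno[1]
    ok[i] <- TRUE
  }
  if (length(dropped_nonstd)) {
    warning("dropped nonstandard residue(s): ",
            paste(unique(dropped_nonstd), collapse = " "))
  }
  if (!any(ok)) stop("no complete protein residues after filtering")
  structure_new(coords[ok, , , drop = FALSE], paste(seq1[ok], collapse = ""),
                ch[ok], rn[ok])
}

#' Write a Structure as PDB text
#'
#' @param structure a `Structure`.
#' @param path output file path, or `NULL` to return the lines.
#' @return invisibly, the character vector of PDB lines.
#' @export
write_backbone <- function(structure, path = NULL) {
  one_to_three <- names(AA_THREE_TO_ONE)[match(strsplit(structure$sequence, "")[[1]],
                                               AA_THREE_TO_ONE)]
  atoms <- c("N", "CA", "C", "O")
  elements <- c("N", "C", "C", "O")
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(structure$n)) {
    for (a in seq_along(atoms)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", atoms[a]), one_to_three[i], structure$chain_id[i],
        structure$resno[i], structure$coords[i, a, 1],
        structure$coords[i, a, 2], structure$coords[i, a, 3], 1, 0,
        elements[a]))
    }
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  out <- character(0)
  for (i in seq_along(seqs)) out <- c(out, paste0(">", names(seqs)[i]), seqs[[i]])
  writeLines(out, path)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path input path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
  names(seqs) <- sub("^>", "", lines[hdr])
  seqs
}

# Build a backbone from per-residue (phi, psi) torsions (degrees), omega fixed
# at 180. Returns L x 4 x 3 coordinate array. phi[1] and psi[L] are unused.
build_backbone <- function(phi, psi) {
  L <- length(phi)
  stopifnot(length(psi) == L, L >= 2)
  d2r <- pi / 180
  coords <- array(NA_real_, c(L, 4, 3))
  # first residue in the xy-plane
  coords[1, 1, ] <- c(0, 0, 0)
  coords[1, 2, ] <- c(.BOND["N_CA"], 0, 0)
  th <- .ANGLE["N_CA_C"] * d2r
  coords[1, 3, ] <- coords[1, 2, ] + .BOND["CA_C"] * c(-cos(th), sin(th), 0)
  for (i in 2:L) {
    coords[i, 1, ] <- place_atom(coords[i - 1, 1, ], coords[i - 1, 2, ],
                                 coords[i - 1, 3, ], .BOND["C_N"],
                                 .ANGLE["CA_C_N"] * d2r, psi[i - 1] * d2r)
    coords[i, 2, ] <- place_atom(coords[i - 1, 2, ], coords[i - 1, 3, ],
                                 coords[i, 1, ], .BOND["N_CA"],
                                 .ANGLE["C_N_CA"] * d2r, pi)  # omega = 180
    coords[i, 3, ] <- place_atom(coords[i - 1, 3, ], coords[i, 1, ],
                                 coords[i, 2, ], .BOND["CA_C"],
                                 .ANGLE["N_CA_C"] * d2r, phi[i] * d2r)
    # carbonyl O of residue i-1, anti to the incoming N
    coords[i - 1, 4, ] <- place_atom(coords[i - 1, 1, ], coords[i - 1, 2, ],
                                     coords[i - 1, 3, ], .BOND["C_O"],
                                     .ANGLE["CA_C_O"] * d2r,
                                     (psi[i - 1] + 180) * d2r)
  }
  coords[L, 4, ] <- place_atom(coords[L, 1, ], coords[L, 2, ], coords[L, 3, ],
                               .BOND["C_O"], .ANGLE["CA_C_O"] * d2r,
                               (psi[L] + 180) * d2r)
  coords
}

#' Build an ideal helix backbone
#'
#' Constructs a polyalanine backbone with constant torsions from ideal bond
#' lengths and angles (omega fixed at 180 degrees). The default
#' (phi, psi) = (-57, -47) gives an alpha-helix with ~1.5 A rise per
#' residue.
#'
#' @param n_res number of residues (>= 2).
#' @param phi,psi backbone torsions in degrees.
#' @return a `Structure` with an all-alanine placeholder sequence.
#' @export
make_ideal_helix <- function(n_res, phi = -57, psi = -47) {
  if (n_res < 2) stop("n_res must be >= 2")
  coords <- build_backbone(rep(phi, n_res), rep(psi, n_res))
  structure_new(coords, strrep("A", n_res))
}

#' Planted sequence-structure rule for synthetic data
#'
#' Defines a burial-based rule used to assign sequences to synthetic
#' backbones: a residue with at least `burial_threshold` other CA atoms
#' within `burial_radius` Angstroms draws its letter uniformly from
#' `hydrophobic_set`, any other residue from `polar_set`; each position is
#' then flipped to a uniform random letter with probability `noise_rate`.
#'
#' @param burial_radius CA-contact radius in Angstroms.
#' @param burial_threshold neighbor count (self excluded) defining burial.
#' @param hydrophobic_set,polar_set disjoint sets of one-letter codes.
#' @param noise_rate flip probability in [0, 1].
#' @return object of class `ToyRule`.
#' @export
toy_rule <- function(burial_radius = 8, burial_threshold = 8,
                     hydrophobic_set = c("I", "L", "V"),
                     polar_set = c("E", "K", "Q"),
                     noise_rate = 0.1) {
  stopifnot(length(intersect(hydrophobic_set, polar_set)) == 0,
            noise_rate >= 0, noise_rate <= 1,
            all(c(hydrophobic_set, polar_set) %in% AA_ALPHABET))
  x <- list(burial_radius = burial_radius, burial_threshold = burial_threshold,
            hydrophobic_set = hydrophobic_set, polar_set = polar_set,
            noise_rate = noise_rate)
  class(x) <- "ToyRule"
  x
}

#' Burial classification under a ToyRule
#' @param structure a `Structure`.
#' @param rule a [toy_rule()].
#' @return logical vector of length L, TRUE where buried.
#' @export
buried_positions <- function(structure, rule) {
  ca <- ca_coords(structure)
  d <- as.matrix(dist(ca))
  counts <- rowSums(d <= rule$burial_radius) - 1L  # exclude self
  counts >= rule$burial_threshold
}

# Assign a sequence by the planted rule (uses the current RNG stream).
.plant_sequence <- function(structure, rule) {
  L <- structure$n
  buried <- buried_positions(structure, rule)
  letters1 <- character(L)
  letters1[buried] <- sample(rule$hydrophobic_set, sum(buried), replace = TRUE)
  letters1[!buried] <- sample(rule$polar_set, sum(!buried), replace = TRUE)
  flip <- runif(L) < rule$noise_rate
  if (any(flip)) letters1[flip] <- sample(AA_ALPHABET, sum(flip), replace = TRUE)
  paste(letters1, collapse = "")
}

# Synthetic backbone archetypes --------------------------------------------

.toy_helix <- function(L, jitter_sd) {
  coords <- build_backbone(rep(-57, L), rep(-47, L))
  coords + array(rnorm(length(coords), sd = jitter_sd), dim(coords))
}

# Antiparallel two-strand sheet as one chain (with a spatial jump between
# strands, recorded as a virtual break).
.toy_hairpin <- function(L, jitter_sd) {
  L1 <- ceiling(L / 2)
  L2 <- L - L1
  s1 <- build_backbone(rep(-135, L1), rep(135, L1))
  s2 <- build_backbone(rep(-135, max(L2, 2)), rep(135, max(L2, 2)))[seq_len(L2), , , drop = FALSE]
  # strand axis of s1 from terminal CAs
  axis1 <- s1[L1, 2, ] - s1[1, 2, ]
  perp <- vunit(vcross(axis1, c(0, 0, 1)))
  if (is.null(perp)) perp <- c(0, 1, 0)
  R <- rotation_about_axis(perp, pi)  # antiparallel
  dim(s2) <- c(L2 * 4, 3)
  s2r <- s2 %*% t(R)
  # align start of strand 2 near the end of strand 1, offset sideways ~4.8 A
  shift <- s1[L1, 2, ] + perp * 4.8 - s2r[2, ]
  s2r <- sweep(s2r, 2, shift, "+")
  dim(s2r) <- c(L2, 4, 3)
  coords <- array(NA_real_, c(L, 4, 3))
  coords[seq_len(L1), , ] <- s1
  coords[L1 + seq_len(L2), , ] <- s2r
  coords + array(rnorm(length(coords), sd = jitter_sd), dim(coords))
}

# Antiparallel two-helix bundle; returns list(coords, chain_id) for either a
# single chain (loopless, virtual break) or two chains.
.toy_bundle <- function(L, jitter_sd, two_chain) {
  L1 <- ceiling(L / 2)
  L2 <- L - L1
  h1 <- build_backbone(rep(-57, L1), rep(-47, L1))
  h2 <- build_backbone(rep(-57, max(L2, 2)), rep(-47, max(L2, 2)))[seq_len(L2), , , drop = FALSE]
  axis1 <- h1[L1, 2, ] - h1[1, 2, ]
  perp <- vunit(vcross(axis1, c(0, 0, 1)))
  if (is.null(perp)) perp <- c(0, 1, 0)
  R <- rotation_about_axis(perp, pi)
  dim(h2) <- c(L2 * 4, 3)
  h2r <- h2 %*% t(R)
  shift <- h1[L1, 2, ] + perp * 9 - h2r[2, ]
  h2r <- sweep(h2r, 2, shift, "+")
  dim(h2r) <- c(L2, 4, 3)
  coords <- array(NA_real_, c(L, 4, 3))
  coords[seq_len(L1), , ] <- h1
  coords[L1 + seq_len(L2), , ] <- h2r
  coords <- coords + array(rnorm(length(coords), sd = jitter_sd), dim(coords))
  chain_id <- if (two_chain) c(rep("A", L1), rep("B", L2)) else rep("A", L)
  list(coords = coords, chain_id = chain_id)
}

#' Generate a synthetic dataset of backbones with planted sequences
#'
#' Structures are jittered ideal helices, two-strand hairpins, or
#' antiparallel two-helix bundles; sequences follow the planted burial rule
#' of `rule`. Deterministic given `seed`.
#'
#' @param n_structures number of structures (>= 1).
#' @param size_range integer interval (min, max) of residue counts.
#' @param rule a [toy_rule()].
#' @param two_chain_fraction probability that a structure is a two-chain
#'   bundle (complex) rather than a single chain.
#' @param seed integer RNG seed.
#' @param jitter_sd coordinate noise in Angstroms.
#' @return list of `Structure` objects.
#' @export
make_toy_dataset <- function(n_structures, size_range = c(24, 48),
                             rule = toy_rule(), two_chain_fraction = 0.3,
                             seed = 1, jitter_sd = 0.15) {
  stopifnot(n_structures >= 1)
  if (length(size_range) != 2 || size_range[2] < size_range[1] || size_range[1] < 8) {
    stop("size_range must be a nondecreasing interval with min >= 8")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  out <- vector("list", n_structures)
  for (s in seq_len(n_structures)) {
    sizes <- seq.int(size_range[1], size_range[2])
    L <- sizes[sample.int(length(sizes), 1)]
    if (runif(1) < two_chain_fraction) {
      b <- .toy_bundle(L, jitter_sd, two_chain = TRUE)
      st <- structure_new(b$coords, strrep("A", L), b$chain_id)
    } else {
      kind <- sample(c("helix", "hairpin", "bundle1"), 1)
      st <- switch(kind,
        helix = structure_new(.toy_helix(L, jitter_sd), strrep("A", L)),
        hairpin = structure_new(.toy_hairpin(L, jitter_sd), strrep("A", L)),
        bundle1 = {
          b <- .toy_bundle(L, jitter_sd, two_chain = FALSE)
          structure_new(b$coords, strrep("A", L), b$chain_id)
        })
    }
    st$sequence <- .plant_sequence(st, rule)
    out[[s]] <- st
  }
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
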