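#' The L19GG poly-leucine backbone
#'
#' The combinatorial library template is a 19-residue poly-leucine helix
#' carrying an invariant GxxxG packing motif near its C-terminus
#' ("L19GG"). Single ionizable residues are introduced at positions
#' 2, 3, 4, 6, 7, 9, 10 or 11 (1-based, N- to C-terminal), i.e. roughly
#' two helical turns upstream of the GxxxG glycines. The exact glycine
#' indices are configurable; all pattern statistics in this package
#' depend only on the randomized positions, not on where the glycines
#' sit.
#'
#' @param gly_positions Integer positions of the two GxxxG glycines
#'   (default `c(14, 18)`); must be 4 apart and outside the randomized
#'   positions.
#' @return A 19-character amino-acid string.
#' @export
#' @examples
#' tmd_backbone()
tmd_backbone <- function(gly_positions = c(14L, 18L)) {
  stopifnot(length(gly_positions) == 2L,
            diff(sort(gly_positions)) == 4L,
            all(gly_positions >= 1 & gly_positions <= 19))
  if (any(gly_positions %in% randomized_positions())) {
    stop("glycines cannot sit on randomized positions")
  }
  s <- rep("L", 19L)
  s[gly_positions] <- "G"
  paste(s, collapse = "")
}

#' @rdname tmd_backbone
#' @export
randomized_positions <- function() c(2L, 3L, 4L, 6L, 7L, 9L, 10L, 11L)

#' @rdname tmd_backbone
#' @export
ionizable_residues <- function() c("D", "E", "K", "R")

#' Build a single-charge library variant
#'
#' Substitutes one ionizable residue (Asp, Glu, Lys or Arg) into the
#' L19GG backbone at one of the randomized positions. `position = NA`
#' returns the unsubstituted wild-type backbone.
#'
#' @param position Integer in `randomized_positions()`, or `NA` for the
#'   wild-type.
#' @param residue One of `"D"`, `"E"`, `"K"`, `"R"`; ignored (must be
#'   `NA`) for the wild-type.
#' @param backbone Backbone sequence (default [tmd_backbone()]).
#' @param backbone_id Label of the backbone (default `"L19GG"`).
#' @return A list of class `tmd_variant` with `variant_id`,
#'   `backbone_id`, `position`, `residue` and `sequence`.
#' @export
#' @examples
#' make_variant(6, "D")$sequence
make_variant <- function(position, residue = NA_character_,
                         backbone = tmd_backbone(),
                         backbone_id = "L19GG") {
  stopifnot(nchar(backbone) == 19L)
  if (is.na(position)) {
    if (!is.na(residue)) stop("wild-type variant takes no residue")
    return(structure(list(
      variant_id = backbone_id, backbone_id = backbone_id,
      position = NA_integer_, residue = NA_character_, sequence = backbone
    ), class = "tmd_variant"))
  }
  position <- as.integer(position)
  if (!position %in% randomized_positions()) {
    stop(sprintf("position %d is not a randomized library position (%s)",
                 position, paste(randomized_positions(), collapse = ", ")))
  }
  if (!residue %in% ionizable_residues()) {
    stop("`residue` must be one of D, E, K, R")
  }
  seq <- backbone
  substr(seq, position, position) <- residue
  structure(list(
    variant_id = sprintf("%s_%s%d", backbone_id, residue, position),
    backbone_id = backbone_id, position = position, residue = residue,
    sequence = seq
  ), class = "tmd_variant")
}

#' @export
print.tmd_variant <- function(x, ...) {
  cat(sprintf("<tmd_variant> %s: %s\n", x$variant_id, x$sequence))
  invisible(x)
}

#' Recover (position, residue) from a variant sequence
#'
#' Inverse of [make_variant()]: compares a 19-mer against the backbone
#' and returns the unique single substitution, or the wild-type when the
#' sequences are identical.
#'
#' @param sequence A 19-character amino-acid string.
#' @inheritParams make_variant
#' @return A `tmd_variant`.
#' @export
parse_variant <- function(sequence, backbone = tmd_backbone(),
                          backbone_id = "L19GG") {
  stopifnot(nchar(sequence) == nchar(backbone))
  a <- strsplit(sequence, "")[[1L]]
  b <- strsplit(backbone, "")[[1L]]
  diff <- which(a != b)
  if (length(diff) == 0L) {
    return(make_variant(NA, backbone = backbone, backbone_id = backbone_id))
  }
  if (length(diff) > 1L) {
    stop("sequence differs from the backbone at more than one position")
  }
  make_variant(diff, a[diff], backbone = backbone, backbone_id = backbone_id)
}

#' Enumerate the full single-charge combinatorial library
#'
#' All 4 ionizable residues at all 8 randomized positions of the L19GG
#' backbone give 32 substituted variants; together with the
#' unsubstituted wild-type each plasmid carries 33 variants. Order is
#' deterministic: wild-type first, then position-major with residues
#' alphabetical.
#'
#' @inheritParams make_variant
#' @return A data.frame of class `tmd_library` with columns
#'   `variant_id`, `position` (`NA` for wild-type), `residue` and
#'   `sequence`; 33 rows.
#' @export
#' @examples
#' nrow(enumerate_library())  # 33
enumerate_library <- function(backbone = tmd_backbone(),
                              backbone_id = "L19GG") {
  grid <- expand.grid(residue = ionizable_residues(),
                      position = randomized_positions(),
                      stringsAsFactors = FALSE)
  variants <- c(
    list(make_variant(NA, backbone = backbone, backbone_id = backbone_id)),
    mapply(make_variant, grid$position, grid$residue,
           MoreArgs = list(backbone = backbone, backbone_id = backbone_id),
           SIMPLIFY = FALSE)
  )
  out <- data.frame(
    variant_id = vapply(variants, `[[`, character(1), "variant_id"),
    position = vapply(variants, `[[`, integer(1), "position"),
    residue = vapply(variants, `[[`, character(1), "residue"),
    sequence = vapply(variants, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("tmd_library", class(out))
  out
}

#' Enumerate all ordered (N-BLa, C-BLa) pairs of the library
#'
#' The two library plasmids are physically distinct, so pairs are
#' ordered: (A, B) and (B, A) are different screen outcomes. The full
#' cross product of a 33-variant library is 1089 pairs.
#'
#' @param library A `tmd_library` (default [enumerate_library()]).
#' @return A data.frame of class `tmd_pairs` with one row per ordered
#'   pair: `n_id`, `n_position`, `n_residue`, `c_id`, `c_position`,
#'   `c_residue` and `observed_count` (initialized to 0). N-side major
#'   order.
#' @export
#' @examples
#' nrow(enumerate_pairs())  # 1089
enumerate_pairs <- function(library = enumerate_library()) {
  stopifnot(is.data.frame(library), nrow(library) >= 1L)
  idx <- expand.grid(c = seq_len(nrow(library)), n = seq_len(nrow(library)))
  out <- data.frame(
    n_id = library$variant_id[idx$n],
    n_position = library$position[idx$n],
    n_residue = library$residue[idx$n],
    c_id = library$variant_id[idx$c],
    c_position = library$position[idx$c],
    c_residue = library$residue[idx$c],
    observed_count = 0L,
    stringsAsFactors = FALSE
  )
  out <- out[order(idx$n, idx$c), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tmd_pairs", class(out))
  out
}

#' Shift a TMD window within its parent sequence context
#'
#' Reporter geometry is sensitive to the rotational orientation of the
#' helix, so screens test register-shifted versions of a TMD: up to
#' three residues are prepended from the natural N-terminal flank while
#' the same number is trimmed from the C-terminus, keeping the window
#' length constant. Shifted constructs are conventionally named
#' `name_+n`.
#'
#' @param parent_context Amino-acid string containing the TMD plus
#'   natural flanking residues.
#' @param window_start 1-based start of the TMD window in
#'   `parent_context`.
#' @param window_len Window length.
#' @param n Shift size, 0 to 3 residues toward the N-terminus.
#' @param name Optional construct name; when given the result is named
#'   `paste0(name, "_+", n)`.
#' @return The shifted window (character scalar, same length).
#' @export
#' @examples
#' shift_orientation("ABCDEFGHIJ", window_start = 4, window_len = 5, n = 1)
shift_orientation <- function(parent_context, window_start, window_len, n,
                              name = NULL) {
  stopifnot(is.character(parent_context), length(parent_context) == 1L)
  if (!(n %in% 0:3)) stop("`n` must be an integer between 0 and 3")
  if (window_start + window_len - 1L > nchar(parent_context)) {
    stop("window extends beyond the parent context")
  }
  new_start <- window_start - n
  if (new_start < 1L) {
    stop("insufficient N-terminal flanking context for the requested shift")
  }
  out <- substr(parent_context, new_start, new_start + window_len - 1L)
  if (!is.null(name)) names(out) <- sprintf("%s_+%d", name, n)
  out
}

# linker expansions used by every screen construct
flexible_linker_default <- function() paste0("SGS", strrep("GGGS", 2L), "GS")
rigid_linker_default <- function() paste0("A", strrep("EAAAK", 5L), "A")

#' Parts list for a split beta-lactamase hybrid protein
#'
#' Each screen construct is, N- to C-terminal: a cleavable signal
#' peptide (directing N-out topology), one beta-lactamase fragment, a
#' flexible linker, the TMD under study, a rigid helical linker, a GFP
#' reporter, and a C-terminal epitope tag. Defaults supply the standard
#' SGS(GGGS)2GS flexible and A(EAAAK)5A rigid linkers and a FLAG tag.
#'
#' @param signal_peptide,bla_fragment,tmd,reporter Amino-acid strings
#'   (non-empty). `tmd` may also be a `tmd_variant`.
#' @param flexible_linker,rigid_linker Linker sequences.
#' @param tag C-terminal tag; `""` to omit.
#' @param bla_fragment_id `"N-BLa"` or `"C-BLa"` (metadata only).
#' @return A list of class `hybrid_parts`.
#' @export
hybrid_parts <- function(signal_peptide, bla_fragment, tmd, reporter,
                         flexible_linker = flexible_linker_default(),
                         rigid_linker = rigid_linker_default(),
                         tag = "DYKDDDDK",
                         bla_fragment_id = c("N-BLa", "C-BLa")) {
  if (inherits(tmd, "tmd_variant")) tmd <- tmd$sequence
  bla_fragment_id <- match.arg(bla_fragment_id)
  parts <- list(signal_peptide = signal_peptide,
                bla_fragment = bla_fragment,
                flexible_linker = flexible_linker, tmd = tmd,
                rigid_linker = rigid_linker, reporter = reporter,
                tag = tag)
  required <- setdiff(names(parts), "tag")
  empty <- vapply(parts[required], nchar, integer(1)) == 0L
  if (any(empty)) {
    stop("empty hybrid part(s): ", paste(required[empty], collapse = ", "))
  }
  structure(c(parts, list(bla_fragment_id = bla_fragment_id)),
            class = "hybrid_parts")
}

#' Assemble a hybrid protein sequence from its parts
#'
#' Concatenates signal peptide, beta-lactamase fragment, flexible
#' linker, TMD, rigid linker, reporter and tag, in that order, after
#' validating that every part uses the 20 standard amino-acid letters.
#'
#' @param parts A [hybrid_parts()] object.
#' @return Amino-acid string; its length is the sum of the part lengths.
#' @export
assemble_hybrid <- function(parts) {
  stopifnot(inherits(parts, "hybrid_parts"))
  segs <- unlist(parts[c("signal_peptide", "bla_fragment",
                         "flexible_linker", "tmd", "rigid_linker",
                         "reporter", "tag")])
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", segs)
  if (any(bad)) {
    stop("non-amino-acid letters in part(s): ",
         paste(names(segs)[bad], collapse = ", "))
  }
  paste(segs, collapse = "")
}

#' Write amino-acid sequences to a FASTA file
#'
#' @param sequences Named character vector of amino-acid sequences (e.g.
#'   a library's `sequence` column named by `variant_id`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Write the library manifest as TSV
#'
#' @param library A `tmd_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_library_manifest <- function(library, path) {
  stopifnot(inherits(library, "tmd_library"))
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
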