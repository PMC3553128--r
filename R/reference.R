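#' Construct a hairpin reference
#'
#' Bundles precursor (hairpin) sequences with the coordinates of their
#' annotated mature arms. A hairpin may carry zero, one or two matures
#' (5p/3p); coordinates are 1-based inclusive on the hairpin, the miRBase
#' convention. Internal interval arithmetic converts to 0-based half-open.
#'
#' @param hairpins Named character vector of hairpin sequences
#'   (A/C/G/T/N only).
#' @param matures Data.frame with columns `hairpin_id`, `mature_id`,
#'   `start`, `end`.
#' @return An object of class `"hairpin_reference"`.
#' @export
hairpin_reference <- function(hairpins, matures) {
  stopifnot(is.character(hairpins), !is.null(names(hairpins)))
  if (any(grepl("[^ACGTN]", hairpins)))
    stop("hairpin sequences may contain only A/C/G/T/N", call. = FALSE)
  if (anyDuplicated(names(hairpins)))
    stop("duplicate hairpin id", call. = FALSE)
  need <- c("hairpin_id", "mature_id", "start", "end")
  stopifnot(is.data.frame(matures), all(need %in% names(matures)))
  matures <- matures[need]
  unknown <- setdiff(matures$hairpin_id, names(hairpins))
  if (length(unknown))
    stop("mature annotation refers to unknown hairpin(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  if (anyDuplicated(matures$mature_id))
    stop("duplicate mature id", call. = FALSE)
  len <- nchar(hairpins)[matures$hairpin_id]
  bad <- matures$start < 1L | matures$start > matures$end | matures$end > len
  if (any(bad))
    stop("mature coordinates outside hairpin for: ",
         paste(matures$mature_id[bad], collapse = ", "), call. = FALSE)
  n_per <- table(matures$hairpin_id)
  if (any(n_per > 2L))
    stop("a hairpin may carry at most two mature arms", call. = FALSE)
  structure(list(hairpins = hairpins, matures = matures),
            class = "hairpin_reference")
}

#' @export
print.hairpin_reference <- function(x, ...) {
  cat("hairpin_reference:", length(x$hairpins), "hairpins,",
      nrow(x$matures), "mature arms\n")
  invisible(x)
}

#' Mature sequence extraction
#'
#' @param ref A `hairpin_reference`.
#' @return Named character vector of mature-arm sequences.
#' @export
mature_sequences <- function(ref) {
  stopifnot(inherits(ref, "hairpin_reference"))
  stats::setNames(
    substr(ref$hairpins[ref$matures$hairpin_id], ref$matures$start,
           ref$matures$end),
    ref$matures$mature_id)
}

#' Write a hairpin reference to FASTA + annotation TSV
#' @param ref A `hairpin_reference`.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisible list of the two paths.
#' @export
write_hairpin_reference <- function(ref, fasta_path, annotation_path) {
  write_fasta(ref$hairpins, fasta_path)
  write_mature_annotations(ref$matures, annotation_path)
  invisible(list(fasta = fasta_path, annotation = annotation_path))
}

#' Read a hairpin reference from FASTA + annotation TSV
#' @param fasta_path,annotation_path Input paths.
#' @return A `hairpin_reference`.
#' @export
read_hairpin_reference <- function(fasta_path, annotation_path) {
  hairpin_reference(read_fasta(fasta_path),
                    read_mature_annotations(annotation_path))
}
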