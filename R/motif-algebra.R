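## Repeat-unit algebra: rotations, reverse complements, primitivity and the
## canonical equivalence classes that make (AAG)n, (GAA)n and (CTT)n one type.

.MOTIF_COMP <- c(A = "T", C = "G", G = "C", T = "A")

.checkMotif <- function(unit) {
    if (!is.character(unit) || length(unit) != 1L || is.na(unit))
        stop("motif must be a single character string")
    unit <- toupper(unit)
    k <- nchar(unit)
    if (k < 1L || k > 6L)
        stop("motif length must be between 1 and 6, got ", k)
    if (grepl("[^ACGT]", unit))
        stop("motif contains characters outside {A,C,G,T}: ", unit)
    unit
}

#' Reverse complement of a repeat unit
#'
#' Watson-Crick complement read in reverse. Applying it twice returns the
#' input.
#'
#' @param unit a repeat unit, 1-6 bp over A/C/G/T (lowercase accepted).
#' @return character(1), the reverse-complement unit.
#' @examples
#' revCompMotif("AAG")   # "CTT"
#' revCompMotif("GCGT")  # "ACGC"
#' @export
revCompMotif <- function(unit) {
    unit <- .checkMotif(unit)
    chars <- strsplit(unit, "", fixed = TRUE)[[1L]]
    paste(rev(.MOTIF_COMP[chars]), collapse = "")
}

#' All cyclic rotations of a repeat unit
#'
#' @inheritParams revCompMotif
#' @return character vector of the distinct cyclic shifts; its length divides
#'   the unit length and equals it exactly when the unit is primitive.
#' @examples
#' motifRotations("AAG")  # "AAG" "AGA" "GAA"
#' @export
motifRotations <- function(unit) {
    unit <- .checkMotif(unit)
    k <- nchar(unit)
    rots <- vapply(seq_len(k) - 1L, function(i) {
        paste0(substr(unit, i + 1L, k), substr(unit, 1L, i))
    }, character(1))
    unique(rots)
}

#' Is a repeat unit primitive?
#'
#' A unit is primitive when it is not a whole-number repetition of a strictly
#' shorter unit (AT is primitive; ATAT = (AT)x2 is not). Non-primitive units
#' never label an SSR: a run of ATAT... is a dinucleotide repeat, not a
#' tetranucleotide one.
#'
#' @inheritParams revCompMotif
#' @return logical(1)
#' @export
isPrimitiveMotif <- function(unit) {
    unit <- .checkMotif(unit)
    k <- nchar(unit)
    for (d in seq_len(k - 1L)) {
        if (k %% d == 0L &&
            strrep(substr(unit, 1L, d), k %/% d) == unit)
            return(FALSE)
    }
    TRUE
}

#' Canonical label of a repeat unit's class
#'
#' The lexicographically smallest string among the unit's cyclic rotations and
#' the rotations of its reverse complement. Two units get the same label iff
#' one is a rotation of the other or of its reverse complement.
#'
#' @inheritParams revCompMotif
#' @return character(1) canonical label.
#' @examples
#' canonicalMotif("CTT")  # "AAG"
#' canonicalMotif("TA")   # "AT"
#' @export
canonicalMotif <- function(unit) {
    unit <- .checkMotif(unit)
    min(c(motifRotations(unit), motifRotations(revCompMotif(unit))))
}

#' The full equivalence class of a primitive repeat unit
#'
#' @inheritParams revCompMotif
#' @return a [MotifClass-class]: all rotations of the unit and of its reverse
#'   complement, labelled by the smallest member.
#' @examples
#' canonicalClass("CTT")   # AAG class: AAG, AGA, GAA, CTT, TTC, TCT
#' canonicalClass("GCAC")  # ACGC class of 8 members
#' @export
canonicalClass <- function(unit) {
    unit <- .checkMotif(unit)
    if (!isPrimitiveMotif(unit))
        stop("unit is not primitive: ", unit)
    members <- unique(c(motifRotations(unit),
                        motifRotations(revCompMotif(unit))))
    new("MotifClass", canonical = min(members), members = members,
        unitLength = nchar(unit))
}

#' Enumerate all motif classes of one unit length
#'
#' Partitions the primitive units of length \code{unitLength} into their
#' rotation/reverse-complement classes. The class counts for unit lengths
#' 1 through 6 are 2, 4, 10, 33, 102 and 350.
#'
#' @param unitLength integer 1-6.
#' @return named list of [MotifClass-class] objects, sorted by canonical
#'   label.
#' @examples
#' length(enumerateMotifClasses(2))  # 4
#' @export
enumerateMotifClasses <- function(unitLength) {
    k <- as.integer(unitLength)
    if (length(k) != 1L || is.na(k) || k < 1L || k > 6L)
        stop("unitLength must be a single integer in 1..6")
    units <- do.call(paste0, expand.grid(
        rep(list(c("A", "C", "G", "T")), k), stringsAsFactors = FALSE))
    units <- units[vapply(units, isPrimitiveMotif, logical(1))]
    canon <- vapply(units, canonicalMotif, character(1))
    reps <- sort(unique(canon))
    out <- lapply(reps, canonicalClass)
    names(out) <- reps
    out
}
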