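MITO_LENGTH <- 16569L

#' Deterministic synthetic rCRS-coordinate reference
#'
#' Builds a synthetic 16,569 nt stand-in for the human mitochondrial reference
#' (rCRS coordinate system). It is *not* the NC_012920 sequence: the bulk of
#' the molecule is a fixed pseudo-random A/C/G/T string, with the loci this
#' package's analyses touch pinned to their rCRS alleles, most importantly the
#' D310 context (C7 at 303-309, T at 310, C5 at 311-315) and the reference
#' alleles at the control-region, MT-ND3 and MDP positions used throughout the
#' documentation and tests (263A, 750A, 1438A, 4769A, 8860A, 15326A, 16519T,
#' 10398A, 3010A, and friends). Coordinates, region windows and variant labels
#' therefore behave exactly as they do against the real reference; users with
#' the genuine NC_012920 FASTA can pass it to [load_reference()] instead.
#'
#' The generator is seed-free and version-stable: an internal linear
#' congruential generator produces the background so the sequence is
#' byte-identical on every platform.
#'
#' @return A [mito_reference] object of length 16,569.
#' @export
synthetic_rcrs <- function() {
  # fixed LCG (Numerical Recipes constants), independent of R's RNG state
  n <- MITO_LENGTH
  x <- 20220915
  draws <- integer(n)
  for (i in seq_len(n)) {
    x <- (1664525 * x + 1013904223) %% 4294967296
    draws[i] <- (x %/% 65536) %% 4   # high bits; low LCG bits are periodic
  }
  bases <- c("A", "C", "G", "T")[draws + 1L]

  # D310 context: ...A A C7 T C5 G C T...
  bases[301:302] <- c("A", "A")
  bases[303:309] <- "C"
  bases[310] <- "T"
  bases[311:315] <- "C"
  bases[316:318] <- c("G", "C", "T")

  pin <- c(
    "263" = "A", "750" = "A", "1438" = "A", "4769" = "A", "8860" = "A",
    "15326" = "A",                      # common backbone polymorphism sites
    "16519" = "T", "16183" = "A", "16189" = "T", "16311" = "T", "16147" = "C",
    "10398" = "A", "3480" = "A", "2275" = "T", "8601" = "A",
    "1346" = "A", "2706" = "A", "2124" = "A", "2145" = "C", "2146" = "A",
    "1709" = "A", "1716" = "A", "1719" = "A", "1736" = "A", "1811" = "A",
    "2445" = "A", "3010" = "A"
  )
  bases[as.integer(names(pin))] <- unname(pin)

  new_mito_reference(paste(bases, collapse = ""), name = "rCRS-synthetic")
}

new_mito_reference <- function(sequence, name) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != MITO_LENGTH) {
    stop("reference length mismatch: expected ", MITO_LENGTH, " nt, got ",
         nchar(sequence), call. = FALSE)
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("reference contains non-ACGT characters", call. = FALSE)
  }
  d310 <- substr(sequence, 303, 315)
  if (d310 != "CCCCCCCTCCCCC") {
    stop("reference lacks the expected D310 context (C7-T-C5 at 303-315)",
         call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence, length = MITO_LENGTH,
         circular = TRUE),
    class = "mito_reference"
  )
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("<mito_reference> ", x$name, ": ", x$length,
      " nt, circular\n", sep = "")
  invisible(x)
}

#' Load the mitochondrial reference from a FASTA file
#'
#' Reads a single-record FASTA and validates it as an rCRS-coordinate
#' mitochondrial reference: exactly 16,569 nt, alphabet A/C/G/T, and the
#' poly-C D310 context (C7-T-C5) at positions 303-315. The packaged default is
#' a synthetic stand-in with rCRS-compatible coordinates (see
#' [synthetic_rcrs()]).
#'
#' @param path Path to a FASTA file with exactly one record. Defaults to the
#'   packaged synthetic reference.
#' @return A `mito_reference` object: list with `name`, `sequence` (uppercase
#'   character string), `length`, and `circular = TRUE`.
#' @examples
#' ref <- load_reference()
#' substr(ref$sequence, 303, 315)  # the D310 tract
#' @export
load_reference <- function(path = system.file("extdata", "rcrs_synthetic.fasta",
                                              package = "mitovar")) {
  recs <- Biostrings::readDNAStringSet(path)
  if (length(recs) != 1L) {
    stop("expected single sequence, found ", length(recs), " records",
         call. = FALSE)
  }
  new_mito_reference(as.character(recs[[1]]), name = names(recs)[1])
}

#' Default region and MDP annotation table
#'
#' Returns the annotated regions used throughout the pipeline: the
#' origin-spanning control region, the two hypervariable regions, the MT-ND3
#' and rRNA genes, and the mitochondrial-derived-peptide (MDP) windows
#' (MOTS-c, Humanin, SHLP1-6) inside the rRNA genes. Coordinates are 1-based
#' inclusive; a region with `start > end` wraps the origin (runs
#' `start..16569` then `1..end`).
#'
#' @param overrides Optional named list; each element is `c(start, end)` and
#'   replaces (or adds) the region of that name.
#' @return A data.frame with columns `name`, `start`, `end`, `category`
#'   (control/HVR1/HVR2/gene/MDP), `wraps_origin`.
#' @examples
#' regions <- region_table()
#' regions[regions$category == "MDP", ]
#' @export
region_table <- function(overrides = NULL) {
  tab <- data.frame(
    name = c("control", "HVR1", "HVR2", "MT-ND3", "MT-RNR1", "MT-RNR2",
             "MOTS-c", "Humanin", "SHLP1", "SHLP2", "SHLP3", "SHLP4",
             "SHLP5", "SHLP6"),
    start = c(16024L, 16024L, 57L, 10059L, 648L, 1669L,
              1343L, 2633L, 2485L, 2088L, 1703L, 2442L, 2780L, 2990L),
    end = c(576L, 16383L, 372L, 10404L, 1601L, 3231L,
            1393L, 2707L, 2559L, 2168L, 1819L, 2522L, 2854L, 3052L),
    category = c("control", "HVR1", "HVR2", "gene", "gene", "gene",
                 rep("MDP", 8)),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    for (nm in names(overrides)) {
      se <- as.integer(overrides[[nm]])
      if (length(se) != 2L || any(is.na(se)) ||
          any(se < 1L) || any(se > MITO_LENGTH)) {
        stop("region override '", nm, "' must be c(start, end) within 1..",
             MITO_LENGTH, call. = FALSE)
      }
      if (nm %in% tab$name) {
        tab[tab$name == nm, c("start", "end")] <- as.list(se)
      } else {
        tab <- rbind(tab, data.frame(name = nm, start = se[1], end = se[2],
                                     category = "gene",
                                     stringsAsFactors = FALSE))
      }
    }
  }
  tab$wraps_origin <- tab$start > tab$end
  tab
}

#' Annotate a reference position with its containing regions
#'
#' @param pos 1-based position in 1..16569.
#' @param regions A region table as returned by [region_table()].
#' @return Character vector of region names containing `pos`, sorted.
#' @examples
#' annotate_position(310)    # control region and HVR2
#' annotate_position(16519)  # control region only (outside HVR1)
#' @export
annotate_position <- function(pos, regions = region_table()) {
  pos <- as.integer(pos)
  if (length(pos) != 1L || is.na(pos) || pos < 1L || pos > MITO_LENGTH) {
    stop("pos must be a single position in 1..", MITO_LENGTH, call. = FALSE)
  }
  hit <- ifelse(regions$wraps_origin,
                pos >= regions$start | pos <= regions$end,
                pos >= regions$start & pos <= regions$end)
  sort(regions$name[hit])
}

#' Export the region table as BED
#'
#' Converts 1-based inclusive intervals to BED's 0-based half-open convention;
#' origin-wrapping regions are split into two BED lines.
#'
#' @param regions A region table ([region_table()]).
#' @param path Output file path.
#' @return Invisibly, the data.frame written (chrom, start, end, name).
#' @export
regions_to_bed <- function(regions, path) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (r$wraps_origin) {
      data.frame(chrom = "chrM",
                 start = c(r$start - 1L, 0L),
                 end = c(MITO_LENGTH, r$end),
                 name = r$name, stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = "chrM", start = r$start - 1L, end = r$end,
                 name = r$name, stringsAsFactors = FALSE)
    }
  })
  bed <- do.call(rbind, rows)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
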