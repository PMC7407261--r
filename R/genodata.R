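#' @include AllClasses.R
NULL

## GT strings accepted for a bi-allelic diploid record; phased separators are
## treated as unphased (the encoding is the alternate-allele count, which is
## symmetric in the two haplotypes).
.gtCode <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)

#' Read a VCF into a GenotypeMatrix
#'
#' Reads a VCF 4.x file (via \pkg{vcfR}) and encodes the per-sample GT field
#' as the alternate-allele count: 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2.
#' Phased separators (\code{|}) are treated as unphased.  Variant ids are
#' formed as \code{chrom:pos:ref:alt}; sample order is preserved from the
#' header.
#'
#' Multi-allelic records are rejected: split them upstream (e.g. with
#' \code{bcftools norm -m-}) into bi-allelic records first.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @param missingPolicy how to resolve missing genotypes (\code{./.}):
#'   \code{"zero"} (default) encodes them as 0 (homozygous reference);
#'   \code{"mode"} imputes the per-variant mode of the observed genotypes
#'   (ties to the smaller value, all-missing variants to 0).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readVCF <- function(path, missingPolicy = c("zero", "mode")) {
  missingPolicy <- match.arg(missingPolicy)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0L) stop("no variant records in ", path)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record at ", fix[which(multi)[1L], "CHROM"], ":",
         fix[which(multi)[1L], "POS"],
         "; split multi-allelic variants into bi-allelic records upstream ",
         "(e.g. bcftools norm -m-) before loading")
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no sample genotype columns")
  samples <- colnames(gt)[-1L]
  ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
               sep = ":")
  ## GT is the first colon-separated field of each genotype entry
  raw <- sub(":.*$", "", gt[, -1L, drop = FALSE])
  raw <- gsub("|", "/", raw, fixed = TRUE)
  miss <- raw == "./." | raw == "." | is.na(raw)
  code <- .gtCode[raw]
  dim(code) <- dim(raw)
  bad <- which(is.na(code) & !miss, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]
    stop("malformed GT '", raw[bad[1L, 1L], bad[1L, 2L]], "' at record ",
         fix[i, "CHROM"], ":", fix[i, "POS"], " sample ",
         samples[bad[1L, 2L]])
  }
  if (any(miss)) {
    if (missingPolicy == "zero") {
      code[miss] <- 0L
    } else {
      for (i in which(rowSums(miss) > 0L)) {
        obs <- code[i, !miss[i, ]]
        code[i, miss[i, ]] <- if (length(obs))
          as.integer(names(which.max(table(factor(obs, 0:2))))) else 0L
      }
    }
  }
  GenotypeMatrix(t(code), variantIds = ids, sampleIds = samples)
}

#' Read a CSV genotype matrix
#'
#' CSV dialect: a header row whose first field names the sample column and
#' whose remaining fields are variant ids; each data row starts with a sample
#' id followed by integer ordinal genotypes.
#'
#' @param path path to the CSV file.
#' @param ordinalMax largest admissible genotype value (default 2, i.e. the
#'   ordinal range \{0,1,2\}).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeCSV <- function(path, ordinalMax = 2L) {
  nf <- unique(utils::count.fields(path, sep = ","))
  if (length(nf) > 1L)
    stop("ragged rows in ", path, ": field counts ",
         paste(nf, collapse = ", "))
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("no samples in ", path)
  if (ncol(df) < 2L) stop("no variant columns in ", path)
  vids <- colnames(df)[-1L]
  if (anyDuplicated(vids))
    stop("duplicate variant id in header: ",
         vids[anyDuplicated(vids)])
  sids <- df[[1L]]
  if (anyDuplicated(sids))
    stop("duplicate sample id: ", sids[anyDuplicated(sids)])
  cells <- as.matrix(df[, -1L, drop = FALSE])
  okInt <- grepl("^-?[0-9]+$", cells)
  dim(okInt) <- dim(cells)
  if (!all(okInt)) {
    bad <- which(!okInt, arr.ind = TRUE)[1L, ]
    stop("non-integer cell '", cells[bad[1L], bad[2L]], "' at sample ",
         sids[bad[1L]], ", variant ", vids[bad[2L]])
  }
  g <- matrix(as.integer(cells), nrow(cells), ncol(cells))
  if (min(g) < 0L || max(g) > ordinalMax)
    stop("genotype values outside the ordinal range {0..", ordinalMax, "}")
  GenotypeMatrix(g, variantIds = vids, sampleIds = sids,
                 ordinalMax = as.integer(ordinalMax))
}

#' Write a GenotypeMatrix as CSV
#'
#' Inverse of \code{\link{readGenotypeCSV}}: a \code{write -> read} round
#' trip reproduces the matrix, ids included.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGenotypeCSV <- function(x, path) {
  stopifnot(is(x, "GenotypeMatrix"))
  df <- data.frame(sample = sampleIds(x), genotypes(x), check.names = FALSE)
  colnames(df) <- c("sample", variantIds(x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a GenotypeMatrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT-only genotypes (0 -> 0/0, 1 -> 0/1,
#' 2 -> 1/1).  Variant ids of the form \code{chrom:pos:ref:alt} are decomposed
#' into the fixed columns; other ids are written on a synthetic contig with
#' consecutive positions.  Requires \code{ordinalMax == 2}.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeVCF <- function(x, path) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (x@ordinalMax != 2L)
    stop("VCF output requires bi-allelic 0/1/2 genotypes")
  ids <- variantIds(x)
  parts <- strsplit(ids, ":", fixed = TRUE)
  canon <- lengths(parts) == 4L
  chrom <- ifelse(canon, vapply(parts, `[`, "", 1L), "1")
  pos <- ifelse(canon, vapply(parts, `[`, "", 2L),
                as.character(seq_along(ids)))
  ref <- ifelse(canon, vapply(parts, `[`, "", 3L), "A")
  alt <- ifelse(canon, vapply(parts, `[`, "", 4L), "T")
  gtStr <- c("0/0", "0/1", "1/1")[genotypes(x) + 1L]
  dim(gtStr) <- dim(genotypes(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleIds(x)), collapse = "\t")),
             con)
  body <- cbind(chrom, pos, ids, ref, alt, ".", ".", ".", "GT", t(gtStr))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read phenotype labels aligned to a sample order
#'
#' Reads a two-column CSV (header \code{sample,label}) and reorders the
#' labels to the supplied sample order.  Class names are the sorted unique
#' labels, mapped to codes \code{0..K-1}.  Samples present in the file but
#' not in \code{samples} are dropped with a warning; samples missing from the
#' file are an error.  A single-class file loads fine (the error surfaces at
#' training time).
#'
#' @param path path to the labels CSV.
#' @param samples ordered character vector of sample ids to align to,
#'   typically \code{sampleIds(genotype_matrix)}.
#' @return A \linkS4class{PhenotypeVector} aligned to \code{samples}.
#' @export
readLabels <- function(path, samples) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("labels CSV needs columns sample,label")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate sample id in labels: ",
                               ids[anyDuplicated(ids)])
  extra <- setdiff(ids, samples)
  if (length(extra)) {
    warning("dropping ", length(extra),
            " labelled sample(s) absent from the genotype data: ",
            paste(head(extra, 5L), collapse = ", "))
    keep <- !(ids %in% extra)
    df <- df[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  pos <- match(samples, ids)
  if (anyNA(pos))
    stop("no label for sample(s): ",
         paste(head(samples[is.na(pos)], 5L), collapse = ", "))
  PhenotypeVector(df[[2L]][pos])
}

#' Partition variants into contiguous column blocks
#'
#' Tiles the variant index range into \code{nBlocks} contiguous spans of
#' near-equal size (sizes differ by at most one, larger blocks first), so
#' block membership is computable from the span alone and reassembling the
#' blocks in order reproduces the matrix exactly.  Deterministic for fixed
#' inputs.
#'
#' @param x a \linkS4class{GenotypeMatrix} (or an integer variant count).
#' @param nBlocks number of blocks, \code{1 <= nBlocks <= nV}.
#' @return List of \linkS4class{ColumnBlock}s.
#' @examples
#' sapply(partitionVariants(10L, 3L), variantSpan)  # sizes 4, 3, 3
#' @export
partitionVariants <- function(x, nBlocks) {
  nV <- if (is(x, "GenotypeMatrix")) nVariants(x) else as.integer(x)
  nBlocks <- as.integer(nBlocks)
  if (nBlocks < 1L || nBlocks > nV)
    stop("need 1 <= nBlocks <= nV (nV = ", nV, ")")
  sizes <- rep(nV %/% nBlocks, nBlocks) +
    c(rep(1L, nV %% nBlocks), rep(0L, nBlocks - nV %% nBlocks))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(nBlocks), function(b)
    new("ColumnBlock", blockIndex = b, start = starts[b],
        end = as.integer(ends[b])))
}

#' Columns owned by a block
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param block a \linkS4class{ColumnBlock} produced by
#'   \code{\link{partitionVariants}}.
#' @return Integer submatrix of the owned columns.
#' @export
blockColumns <- function(x, block) {
  stopifnot(is(x, "GenotypeMatrix"), is(block, "ColumnBlock"))
  genotypes(x)[, variantSpan(block), drop = FALSE]
}
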