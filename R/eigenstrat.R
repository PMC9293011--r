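#' Genotype matrix container
#'
#' Bundles an individuals-by-markers genotype table (codes 0/1/2 with 9 for
#' missing) with marker metadata (chromosome, genetic position in Morgans,
#' physical position, alleles) and individual metadata (id, sex, group label).
#' Pseudo-haploid matrices carry only 0/2/9 calls: a single sampled allele
#' reported as a homozygous genotype, the standard representation for
#' low-coverage ancient DNA.
#'
#' @param calls integer matrix, individuals in rows, markers in columns,
#'   values in \{0, 1, 2, 9\}.
#' @param snp data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{gpos} (Morgans), \code{ppos}, \code{ref}, \code{alt}.
#' @param ind data.frame with columns \code{ind_id}, \code{sex},
#'   \code{group}.
#' @param ploidy \code{"diploid"} or \code{"pseudo_haploid"}.
#' @return An object of class \code{geno_matrix}.
#' @export
geno_matrix <- function(calls, snp, ind, ploidy = c("diploid", "pseudo_haploid")) {
  ploidy <- match.arg(ploidy)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(snp), is.data.frame(ind))
  snp$chrom <- as.character(snp$chrom)
  snp$snp_id <- as.character(snp$snp_id)
  ind$ind_id <- as.character(ind$ind_id)
  if (nrow(calls) != nrow(ind))
    stop("geno_matrix: ", nrow(calls), " call rows but ", nrow(ind), " individuals")
  if (ncol(calls) != nrow(snp))
    stop("geno_matrix: ", ncol(calls), " call columns but ", nrow(snp), " markers")
  bad <- !(calls %in% c(0L, 1L, 2L, 9L))
  if (any(bad))
    stop("geno_matrix: invalid genotype code(s): ",
         paste(unique(calls[bad]), collapse = ", "))
  if (ploidy == "pseudo_haploid" && any(calls == 1L))
    stop("geno_matrix: pseudo-haploid matrix contains heterozygous calls (1)")
  if (anyDuplicated(snp$snp_id))
    stop("geno_matrix: duplicated snp_id")
  if (anyDuplicated(ind$ind_id))
    stop("geno_matrix: duplicated ind_id")
  if (any(!is.finite(snp$gpos)) || any(snp$gpos < 0))
    stop("geno_matrix: genetic positions must be finite and non-negative")
  rownames(calls) <- ind$ind_id
  colnames(calls) <- snp$snp_id
  structure(list(calls = calls, snp = snp, ind = ind, ploidy = ploidy),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$ind), "individuals x", nrow(x$snp), "markers (",
      x$ploidy, ")\n")
  cat("  chromosomes:", paste(unique(x$snp$chrom), collapse = " "), "\n")
  cat("  missing rate:", format(mean(x$calls == 9L), digits = 3), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

# group markers by chromosome (order of first appearance) and sort by
# genetic position within each chromosome; returns new column order
.snp_order <- function(snp) {
  order(match(snp$chrom, unique(snp$chrom)), snp$gpos)
}

#' Read an EIGENSTRAT text triplet
#'
#' Parses .geno/.snp/.ind files in the text (ancestrymap-style) EIGENSTRAT
#' dialect: one line per marker in .geno with one genotype character per
#' individual; whitespace-delimited .snp with id, chromosome, genetic
#' position (Morgans), physical position and optionally the two alleles;
#' whitespace-delimited .ind with id, sex (accepted and ignored beyond
#' storage) and group label. Markers unsorted within a chromosome are sorted
#' by genetic position with a warning, since pair-distance binning requires
#' monotone positions. Chromosome labels are opaque strings; any number of
#' chromosomes is supported.
#'
#' @param geno_path,snp_path,ind_path paths to the three files.
#' @param ploidy declared ploidy of the calls; \code{"pseudo_haploid"}
#'   requires every non-missing call to be 0 or 2.
#' @return A \code{\link{geno_matrix}}.
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path,
                            ploidy = c("diploid", "pseudo_haploid")) {
  ploidy <- match.arg(ploidy)
  for (p in c(geno_path, snp_path, ind_path))
    if (!file.exists(p)) stop("file not found: ", p)

  snp_raw <- utils::read.table(text = readLines(snp_path, warn = FALSE),
                               header = FALSE, colClasses = "character",
                               col.names = paste0("V", 1:6), fill = TRUE,
                               strip.white = TRUE)
  if (ncol(snp_raw) < 4) stop(".snp file must have at least 4 columns")
  snp <- data.frame(snp_id = snp_raw$V1, chrom = snp_raw$V2,
                    gpos = as.numeric(snp_raw$V3),
                    ppos = as.integer(as.numeric(snp_raw$V4)),
                    ref = if ("V5" %in% names(snp_raw)) snp_raw$V5 else NA_character_,
                    alt = if ("V6" %in% names(snp_raw)) snp_raw$V6 else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(is.na(snp$gpos)))
    stop(".snp: non-numeric genetic position at row ",
         which(is.na(snp$gpos))[1])

  ind_lines <- readLines(ind_path, warn = FALSE)
  ind_lines <- ind_lines[nzchar(trimws(ind_lines))]
  if (length(ind_lines) == 0) {
    ind <- data.frame(ind_id = character(), sex = character(),
                      group = character(), stringsAsFactors = FALSE)
  } else {
    ind_raw <- utils::read.table(text = ind_lines, header = FALSE,
                                 colClasses = "character", strip.white = TRUE)
    if (ncol(ind_raw) < 3) stop(".ind file must have 3 columns (id, sex, group)")
    ind <- data.frame(ind_id = ind_raw[[1]], sex = ind_raw[[2]],
                      group = ind_raw[[3]], stringsAsFactors = FALSE)
  }

  lines <- readLines(geno_path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  if (nrow(ind) > 0) lines <- lines[nzchar(lines)]
  if (length(lines) != nrow(snp))
    stop(".geno has ", length(lines), " marker rows but .snp has ",
         nrow(snp), " rows")
  widths <- nchar(lines)
  if (any(widths != nrow(ind))) {
    r <- which(widths != nrow(ind))[1]
    stop(".geno row ", r, " has width ", widths[r], " but .ind has ",
         nrow(ind), " individuals")
  }
  chars <- unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE)
  ok <- chars %in% c("0", "1", "2", "9")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(".geno: invalid genotype character '", chars[bad], "' at marker row ",
         ((bad - 1) %/% nrow(ind)) + 1, ", individual column ",
         ((bad - 1) %% nrow(ind)) + 1)
  }
  # .geno rows are markers; internal layout is individuals x markers
  calls <- matrix(as.integer(chars), nrow = nrow(ind), ncol = nrow(snp))

  ord <- .snp_order(snp)
  if (!identical(ord, seq_len(nrow(snp)))) {
    warning("markers re-sorted by genetic position within chromosomes")
    snp <- snp[ord, , drop = FALSE]
    rownames(snp) <- NULL
    calls <- calls[, ord, drop = FALSE]
  }
  geno_matrix(calls, snp, ind, ploidy)
}

#' Write an EIGENSTRAT text triplet
#'
#' Emits \code{<prefix>.geno}, \code{<prefix>.snp} and \code{<prefix>.ind}
#' readable by \code{\link{read_eigenstrat}}; a read/write round trip
#' preserves all fields.
#'
#' @param gm a \code{\link{geno_matrix}}.
#' @param prefix output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_eigenstrat <- function(gm, prefix) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (gm$ploidy == "pseudo_haploid" && any(gm$calls == 1L))
    stop("refusing to write pseudo-haploid matrix containing heterozygous calls")
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  geno_lines <- if (nrow(gm$calls) == 0L) rep("", 0L) else
    apply(gm$calls, 2, paste, collapse = "")
  # 0 individuals: .geno still needs one (empty) row per marker
  if (nrow(gm$calls) == 0L) geno_lines <- rep("", ncol(gm$calls))
  writeLines(geno_lines, paths[1])
  snp <- gm$snp
  writeLines(sprintf("%s\t%s\t%.10g\t%d\t%s\t%s", snp$snp_id, snp$chrom,
                     snp$gpos, snp$ppos,
                     ifelse(is.na(snp$ref), "A", snp$ref),
                     ifelse(is.na(snp$alt), "G", snp$alt)),
             paths[2])
  writeLines(sprintf("%s\t%s\t%s", gm$ind$ind_id, gm$ind$sex, gm$ind$group),
             paths[3])
  invisible(paths)
}

#' Subset a genotype matrix by individual or group
#'
#' @param gm a \code{\link{geno_matrix}}.
#' @param who character vector matched against \code{ind_id} first, then
#'   against group labels; an entry matching neither is an error.
#' @return A \code{geno_matrix} restricted to the selected individuals.
#' @export
subset_individuals <- function(gm, who) {
  stopifnot(inherits(gm, "geno_matrix"))
  who <- as.character(who)
  sel <- logical(nrow(gm$ind))
  for (w in who) {
    hit <- gm$ind$ind_id == w | gm$ind$group == w
    if (!any(hit)) stop("no individual or group matches '", w, "'")
    sel <- sel | hit
  }
  geno_matrix(gm$calls[sel, , drop = FALSE], gm$snp,
              gm$ind[sel, , drop = FALSE], gm$ploidy)
}

#' Per-marker allele frequencies of a reference panel
#'
#' Counts alleles over the selected individuals: a diploid call contributes
#' its dosage out of 2 observed alleles, a pseudo-haploid call one allele.
#' Markers with zero observations are flagged unavailable.
#'
#' @param gm a \code{\link{geno_matrix}}.
#' @param individuals optional ids/groups to subset first.
#' @param label panel label carried through to reports.
#' @return An object of class \code{freq_panel}: list with \code{freq}
#'   (frequency in \[0,1\], NA where unavailable), \code{count} (observed
#'   allele count), \code{ok} (availability mask) and the marker table.
#' @export
allele_frequencies <- function(gm, individuals = NULL, label = "ref") {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!is.null(individuals)) gm <- subset_individuals(gm, individuals)
  if (nrow(gm$ind) == 0L) stop("allele_frequencies: no individuals selected")
  g <- gm$calls
  obs <- g != 9L
  per_call <- if (gm$ploidy == "diploid") 2L else 1L
  count <- unname(colSums(obs)) * per_call
  dosage <- unname(colSums(ifelse(obs, g, 0L))) /
    (if (gm$ploidy == "diploid") 1 else 2)
  freq <- ifelse(count > 0L, dosage / count, NA_real_)
  structure(list(freq = freq, count = as.integer(count), ok = count > 0L,
                 snp = gm$snp, label = label, n_ind = nrow(gm$ind)),
            class = "freq_panel")
}

#' @export
print.freq_panel <- function(x, ...) {
  cat("freq_panel '", x$label, "': ", length(x$freq), " markers from ",
      x$n_ind, " individuals; ", sum(!x$ok), " unavailable\n", sep = "")
  invisible(x)
}

#' Read a two-column sampling-age table
#'
#' EIGENSTRAT .ind files carry no sampling age, so ages (years before
#' present) are supplied separately as whitespace-delimited
#' \code{ind_id age_BP} rows. Present-day samples have age 0.
#'
#' @param path table path.
#' @return Named numeric vector of ages keyed by individual id.
#' @export
read_age_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = c("character", "numeric"),
                           strip.white = TRUE)
  ages <- tab[[2]]
  if (any(!is.finite(ages)) || any(ages < 0))
    stop("sampling ages must be finite and non-negative")
  names(ages) <- tab[[1]]
  ages
}
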