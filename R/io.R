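#' @include containers.R
NULL

UNKNOWN_PARENT <- "0"

# Topological sort of a pedigree so parents precede offspring.
# Errors on cycles (an animal that is its own ancestor).
sortPedigree <- function(pedigree) {
  n <- nrow(pedigree)
  placed <- logical(n)
  known <- character(0)
  order <- integer(0)
  remaining <- seq_len(n)
  while (length(remaining) > 0) {
    ready <- remaining[(pedigree$sire[remaining] %in%
                          c(UNKNOWN_PARENT, known)) &
                       (pedigree$dam[remaining] %in%
                          c(UNKNOWN_PARENT, known))]
    if (length(ready) == 0)
      stop("pedigree contains a cycle (an animal is its own ancestor) ",
           "or a parent missing from the animal column: ",
           paste(head(pedigree$animal[remaining]), collapse = ", "))
    order <- c(order, ready)
    known <- c(known, pedigree$animal[ready])
    remaining <- setdiff(remaining, ready)
  }
  pedigree[order, , drop = FALSE]
}

checkPedigree <- function(ped) {
  req <- c("animal", "sire", "dam")
  if (!all(req %in% colnames(ped)))
    stop("pedigree must have columns animal, sire, dam")
  if (anyDuplicated(ped$animal))
    stop("duplicate animal rows in pedigree: ",
         paste(head(unique(ped$animal[duplicated(ped$animal)])),
               collapse = ", "))
  if (any(ped$animal == ped$sire | ped$animal == ped$dam))
    stop("animal listed as its own parent")
  parents <- setdiff(c(ped$sire, ped$dam), UNKNOWN_PARENT)
  orphans <- setdiff(parents, ped$animal)
  if (length(orphans) > 0)
    stop("parents missing from the animal column: ",
         paste(head(orphans), collapse = ", "))
  invisible(sortPedigree(ped))   # raises on cycles
}

#' Read a pedigree CSV
#'
#' Expects a header with columns `animal`, `sire`, `dam` and optionally
#' `birth_year` and `sex`. The sentinel `"0"` (or an empty field) denotes
#' an unknown parent; an animal must have either both or neither parent
#' unknown for the simulator, but mixed records are accepted here. The
#' pedigree is checked to be acyclic with all named parents present.
#'
#' @param path CSV file path.
#' @return pedigree data.frame with character ids and the sentinel `"0"`.
#' @export
readPedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (col in c("animal", "sire", "dam"))
    if (!col %in% colnames(ped))
      stop("pedigree file must have column '", col, "'")
  ped$sire[is.na(ped$sire) | ped$sire == ""] <- UNKNOWN_PARENT
  ped$dam[is.na(ped$dam) | ped$dam == ""] <- UNKNOWN_PARENT
  if ("birth_year" %in% colnames(ped))
    ped$birth_year <- as.integer(ped$birth_year)
  checkPedigree(ped)
  ped
}

#' Write a pedigree CSV
#' @param pedigree pedigree data.frame.
#' @param path output path.
#' @export
writePedigree <- function(pedigree, path) {
  utils::write.csv(pedigree, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype CSV
#'
#' Expects a header with `animal`, `trait`, `value` plus the
#' contemporary-group factor columns (typically `flock`, `birth_year`,
#' `sex`, `mob`). One record per animal x trait is enforced.
#'
#' @param path CSV file path.
#' @return phenotype data.frame; factor columns stay character.
#' @export
readPhenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("animal", "trait", "value"))
    if (!col %in% colnames(ph))
      stop("phenotype file must have column '", col, "'")
  ph$animal <- as.character(ph$animal)
  if (anyDuplicated(ph[, c("animal", "trait")]))
    stop("duplicate animal x trait records in phenotype file")
  ph
}

#' Write a phenotype CSV
#' @param phenotypes phenotype data.frame.
#' @param path output path.
#' @export
writePhenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes from PLINK text or dosage CSV
#'
#' Two dialects are supported behind the same [GenotypeMatrix-class]
#' contract:
#' \describe{
#'   \item{`dosage_csv`}{header row of SNP ids, first column the animal id,
#'     cells in `{0, 1, 2, NA}`. A companion `<path>.map` CSV with columns
#'     `snp_id`, `chrom`, `pos` is used when present.}
#'   \item{`ped_map`}{standard 6 leading PED columns then two allele
#'     columns per SNP coded `A`/`B` (`0` = missing); the `.map` companion
#'     supplies `chrom`, `snp_id`, genetic distance and 1-based position.
#'     The dosage counts the `"A"` allele.}
#' }
#'
#' @param path path to the `.csv` or `.ped` file.
#' @param dialect `"dosage_csv"` or `"ped_map"`.
#' @return a [GenotypeMatrix-class]; allele frequencies come from
#'   non-missing calls via [alleleFreqs()].
#' @export
readGenotypes <- function(path, dialect = c("dosage_csv", "ped_map")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (dialect == "dosage_csv") readDosageCsv(path) else readPedMap(path)
}

readDosageCsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty dosage file: ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- fields[[1]]
  snpIds <- header[-1]
  if (anyDuplicated(snpIds))
    stop("duplicate SNP ids in header of ", path)
  nc <- lengths(fields)
  bad <- which(nc != length(header))
  if (length(bad) > 0)
    stop("ragged row in ", path, " at line ", bad[1])
  body <- fields[-1]
  ids <- vapply(body, `[[`, character(1), 1)
  cells <- t(vapply(body, function(f) f[-1],
                    character(length(snpIds))))
  if (length(snpIds) == 1) cells <- matrix(cells, ncol = 1)
  ok <- cells %in% c("0", "1", "2", "NA", "")
  if (!all(ok)) {
    badcell <- which(!matrix(ok, nrow(cells)), arr.ind = TRUE)[1, ]
    stop("non-dosage code '", cells[badcell[1], badcell[2]], "' at line ",
         badcell[1] + 1, " of ", path)
  }
  dos <- matrix(suppressWarnings(as.numeric(cells)), nrow(cells),
                dimnames = list(ids, snpIds))
  mapPath <- paste0(path, ".map")
  map <- NULL
  if (file.exists(mapPath)) {
    m <- utils::read.csv(mapPath, stringsAsFactors = FALSE)
    map <- m[match(snpIds, m$snp_id), c("chrom", "pos")]
  }
  GenotypeMatrix(dos, map = map, animalIds = ids, snpIds = snpIds)
}

readPedMap <- function(path) {
  mapPath <- sub("\\.ped$", ".map", path)
  if (identical(mapPath, path) || !file.exists(mapPath))
    stop("companion .map file not found for ", path)
  map <- utils::read.table(mapPath, stringsAsFactors = FALSE)
  if (ncol(map) != 4)
    stop(".map must have 4 columns (chrom, snp_id, cM, pos)")
  colnames(map) <- c("chrom", "snp_id", "cm", "pos")
  if (anyDuplicated(map$snp_id))
    stop("duplicate SNP ids in ", mapPath)
  lines <- readLines(path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6 + 2 * nrow(map)
  bad <- which(lengths(fields) != want)
  if (length(bad) > 0)
    stop("ragged row in ", path, " at line ", bad[1], " (expected ", want,
         " fields)")
  ids <- vapply(fields, `[[`, character(1), 2)   # within-family id
  alleles <- t(vapply(fields, function(f) f[-(1:6)],
                      character(2 * nrow(map))))
  okCode <- alleles %in% c("A", "B", "0")
  if (!all(okCode)) {
    badcell <- which(!matrix(okCode, nrow(alleles)), arr.ind = TRUE)[1, ]
    stop("non-biallelic code '", alleles[badcell[1], badcell[2]],
         "' at line ", badcell[1], " of ", path)
  }
  a1 <- alleles[, seq(1, ncol(alleles), 2), drop = FALSE]
  a2 <- alleles[, seq(2, ncol(alleles), 2), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  dos <- (a1 == "A") + (a2 == "A")
  dos[miss] <- NA
  dimnames(dos) <- list(ids, map$snp_id)
  GenotypeMatrix(dos, map = map[, c("chrom", "pos")], animalIds = ids,
                 snpIds = map$snp_id)
}

#' Write genotypes in a supported dialect
#'
#' @param geno a [GenotypeMatrix-class].
#' @param path output path (`.csv` for `dosage_csv`, `.ped` for
#'   `ped_map`; companions `<path>.map` / `.map` are written alongside).
#' @param dialect `"dosage_csv"` or `"ped_map"`.
#' @export
writeGenotypes <- function(geno, path,
                           dialect = c("dosage_csv", "ped_map")) {
  dialect <- match.arg(dialect)
  d <- dosages(geno)
  map <- snpMap(geno)
  if (dialect == "dosage_csv") {
    if (any(!is.na(d) & d != round(d)))
      stop("dosage_csv stores integer dosages; matrix has imputed values")
    header <- paste(c("animal", colnames(d)), collapse = ",")
    rows <- vapply(seq_len(nrow(d)), function(i)
      paste(c(rownames(d)[i], ifelse(is.na(d[i, ]), "NA",
                                     format(d[i, ], trim = TRUE))),
            collapse = ","), character(1))
    writeLines(c(header, rows), path)
    utils::write.csv(data.frame(snp_id = map$snp_id, chrom = map$chrom,
                                pos = map$pos),
                     paste0(path, ".map"), row.names = FALSE, quote = FALSE)
  } else {
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, "A", "B"))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, "A", "B"))
    rows <- vapply(seq_len(nrow(d)), function(i) {
      al <- as.vector(rbind(a1[i, ], a2[i, ]))
      paste(c("FAM", rownames(d)[i], "0", "0", "0", "-9", al),
            collapse = " ")
    }, character(1))
    writeLines(rows, path)
    mp <- data.frame(chrom = map$chrom, snp_id = map$snp_id, cm = 0,
                     pos = map$pos)
    utils::write.table(mp, sub("\\.ped$", ".map", path),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write an accuracy report as TSV and JSON
#'
#' One TSV row per trait x scenario with the observed accuracy, group
#' sizes, expected accuracy, ENP and K factor; a JSON file mirrors the same
#' rows exactly (plus the per-group detail).
#'
#' @param report an [AccuracyReport-class].
#' @param path base output path; `<path>.tsv` and `<path>.json` are
#'   written.
#' @return invisibly, the two file paths.
#' @export
writeReport <- function(report, path) {
  rows <- reportRows(report)
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(rows, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(rows = rows, groups = report@groups,
                            skipped = report@skipped),
                       json, dataframe = "rows", digits = NA,
                       na = "null")
  invisible(c(tsv = tsv, json = json))
}

#' Read back the JSON side of a written report
#' @param path the `.json` path written by [writeReport()].
#' @return list with `rows`, `groups` and `skipped` data.frames.
#' @export
readReport <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
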