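#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the package's S4 containers.
#' `animalIds()` returns the animal identifiers in storage order,
#' `dosages()` the animals-by-SNPs dosage matrix, `snpMap()` the per-SNP
#' map, `alleleFreqs()` per-SNP counted-allele frequencies, `kind()` the
#' provenance tag of a relationship matrix, and `mbv()`, `pev()`,
#' `accTheoretical()` the GBLUP solution components.
#'
#' @param x an object of the documented class.
#' @return the accessed component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname accessors
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

#' @rdname accessors
#' @export
setGeneric("kind", function(x) standardGeneric("kind"))

#' @rdname accessors
#' @export
setGeneric("blendWeight", function(x) standardGeneric("blendWeight"))

#' @rdname accessors
#' @export
setGeneric("mbv", function(x) standardGeneric("mbv"))

#' @rdname accessors
#' @export
setGeneric("pev", function(x) standardGeneric("pev"))

#' @rdname accessors
#' @export
setGeneric("accTheoretical", function(x) standardGeneric("accTheoretical"))

#' @rdname accessors
#' @export
setGeneric("overallMean", function(x) standardGeneric("overallMean"))

#' @rdname accessors
#' @export
setGeneric("sigma2A", function(x) standardGeneric("sigma2A"))

#' @rdname accessors
#' @export
setGeneric("sigma2E", function(x) standardGeneric("sigma2E"))

#' @rdname accessors
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname accessors
#' @export
setGeneric("adjustedValues", function(x) standardGeneric("adjustedValues"))

#' @rdname accessors
#' @export
setGeneric("reportRows", function(x) standardGeneric("reportRows"))
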