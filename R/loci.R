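#' @importFrom GenomicRanges GRanges mcols mcols<- start end width seqnames
#'   GRangesList findOverlaps pintersect
#' @importFrom IRanges IRanges overlapsAny
NULL

#' Construct a CNV locus definition
#'
#' A locus definition is a critical genomic interval (1-based, inclusive)
#' together with the dosage type that makes it pathogenic, its category
#' (schizophrenia-associated or otherwise pathogenic for neurodevelopmental
#' disorders), and the sub-intervals that drive call matching: key genes
#' that a matching CNV must fully contain, or, for single-gene loci, the
#' gene span and its exons.
#'
#' @param name locus name, e.g. `"15q11.2del"`.
#' @param chrom chromosome label.
#' @param start,end critical-interval coordinates, 1-based inclusive.
#' @param dosage `"del"` or `"dup"`.
#' @param category `"scz_associated"` or `"pathogenic_other"`.
#' @param keyGenes optional [GenomicRanges::GRanges] of key genes, each
#'   contained in the critical interval.
#' @param singleGene logical; if TRUE, `geneSpan` and `exons` are required
#'   and the exon/whole-gene matching rules apply instead of the
#'   half-interval rule.
#' @param geneSpan GRanges of length 1 spanning the gene (single-gene loci).
#' @param exons GRanges of the gene's exons (single-gene loci), all within
#'   `geneSpan`.
#' @return A `GRanges` of length 1 carrying the definition in its metadata
#'   columns; combine several with `c()`.
#' @examples
#' locusDefinition("toy_del", "chr1", 1000, 2000, "del")
#' @export
locusDefinition <- function(name, chrom, start, end, dosage,
                            category = "scz_associated",
                            keyGenes = NULL, singleGene = FALSE,
                            geneSpan = NULL, exons = NULL) {
    assertThat(end >= start, "locus '%s': end < start", name)
    assertThat(dosage %in% c("del", "dup"),
               "locus '%s': dosage must be 'del' or 'dup'", name)
    assertThat(category %in% c("scz_associated", "pathogenic_other"),
               "locus '%s': unknown category '%s'", name, category)
    crit <- GRanges(chrom, IRanges(start, end))
    if (is.null(keyGenes)) keyGenes <- GRanges()
    if (singleGene) {
        assertThat(!is.null(geneSpan) && length(geneSpan) == 1L,
                   "locus '%s': single-gene locus needs a geneSpan", name)
        assertThat(!is.null(exons) && length(exons) >= 1L,
                   "locus '%s': single-gene locus needs exons", name)
        assertThat(all(start(exons) >= start(geneSpan)) &&
                   all(end(exons) <= end(geneSpan)),
                   "locus '%s': exons must lie within geneSpan", name)
    } else {
        geneSpan <- GRanges()
        exons <- GRanges()
        if (length(keyGenes))
            assertThat(all(start(keyGenes) >= start) &&
                       all(end(keyGenes) <= end),
                       "locus '%s': key genes must lie within the critical interval",
                       name)
    }
    mcols(crit) <- S4Vectors::DataFrame(
        locus = name, dosage = dosage, category = category,
        single_gene = singleGene,
        key_genes = GRangesList(keyGenes),
        gene_span = GRangesList(geneSpan),
        exons = GRangesList(exons))
    names(crit) <- name
    crit
}

.grFromJson <- function(x) {
    if (is.null(x) || length(x) == 0) return(NULL)
    if (!is.null(x$chrom)) x <- list(x)    # single interval object
    GRanges(vapply(x, `[[`, "", "chrom"),
            IRanges(vapply(x, function(e) as.numeric(e$start), 0),
                    vapply(x, function(e) as.numeric(e$end), 0)))
}

#' Read locus definitions from JSON
#'
#' The file is an array of objects with fields `name`, `chrom`, `start`,
#' `end`, `dosage`, `category`, and optionally `key_genes` (array of
#' `{chrom,start,end}`), `single_gene`, `gene_span`, `exons`.
#'
#' @param path path to the JSON file.
#' @return a `GRanges` of locus definitions (see [locusDefinition()]).
#' @seealso [defaultLoci()] for the bundled synthetic locus set.
#' @export
readLocusDefinitions <- function(path) {
    defs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    assertThat(length(defs) > 0, "no locus definitions in %s", path)
    out <- lapply(defs, function(d) {
        locusDefinition(d$name, d$chrom, as.numeric(d$start),
                        as.numeric(d$end), d$dosage,
                        category = d$category %||% "scz_associated",
                        keyGenes = .grFromJson(d$key_genes),
                        singleGene = isTRUE(d$single_gene),
                        geneSpan = .grFromJson(d$gene_span),
                        exons = .grFromJson(d$exons))
    })
    ## loci live on different chromosomes by design; the combine warning
    ## about disjoint seqlevels is expected
    suppressWarnings(do.call(c, out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled synthetic CNV locus set
#'
#' A synthetic stand-in for a curated table of schizophrenia-associated and
#' other neurodevelopmental CNV loci: approximate GRCh37 critical-region
#' coordinates for eight SCZ-associated loci (including the single-gene
#' NRXN1 locus, 2p16.3) and five other pathogenic loci. Coordinates and
#' sub-intervals are illustrative, not curated breakpoints; the file is
#' `extdata/scz_loci_synthetic.json`.
#'
#' @return a `GRanges` of locus definitions.
#' @examples
#' loci <- defaultLoci()
#' table(mcols(loci)$category)
#' @export
defaultLoci <- function() {
    readLocusDefinitions(system.file("extdata", "scz_loci_synthetic.json",
                                     package = "cnvCortex", mustWork = TRUE))
}
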