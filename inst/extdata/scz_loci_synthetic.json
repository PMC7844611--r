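[
  {
    "name": "1q21.1del", "chrom": "chr1",
    "start": 146570001, "end": 147390000,
    "dosage": "del", "category": "scz_associated",
    "key_genes": [
      {"chrom": "chr1", "start": 147220001, "end": 147240000}
    ]
  },
  {
    "name": "1q21.1dup", "chrom": "chr1",
    "start": 146570001, "end": 147390000,
    "dosage": "dup", "category": "scz_associated",
    "key_genes": [
      {"chrom": "chr1", "start": 147220001, "end": 147240000}
    ]
  },
  {
    "name": "2p16.3del", "chrom": "chr2",
    "start": 50145001, "end": 51260000,
    "dosage": "del", "category": "scz_associated",
    "single_gene": true,
    "gene_span": {"chrom": "chr2", "start": 50145001, "end": 51260000},
    "exons": [
      {"chrom": "chr2", "start": 50150001, "end": 50151500},
      {"chrom": "chr2", "start": 50280001, "end": 50280200},
      {"chrom": "chr2", "start": 50420001, "end": 50420180},
      {"chrom": "chr2", "start": 50650001, "end": 50650300},
      {"chrom": "chr2", "start": 50850001, "end": 50850150},
      {"chrom": "chr2", "start": 51044001, "end": 51044200},
      {"chrom": "chr2", "start": 51160001, "end": 51160400},
      {"chrom": "chr2", "start": 51258001, "end": 51260000}
    ]
  },
  {
    "name": "3q29del", "chrom": "chr3",
    "start": 195720001, "end": 197350000,
    "dosage": "del", "category": "scz_associated",
    "key_genes": [
      {"chrom": "chr3", "start": 196640001, "end": 196680000}
    ]
  },
  {
    "name": "15q11.2del", "chrom": "chr15",
    "start": 22805001, "end": 23090000,
    "dosage": "del", "category": "scz_associated",
    "key_genes": [
      {"chrom": "chr15", "start": 22892001, "end": 23003000}
    ]
  },
  {
    "name": "15q13.3del", "chrom": "chr15",
    "start": 30910001, "end": 32480000,
    "dosage": "del", "category": "scz_associated",
    "key_genes": [
      {"chrom": "chr15", "start": 32322001, "end": 32462000}
    ]
  },
  {
    "name": "16p11.2dup", "chrom": "chr16",
    "start": 29650001, "end": 30200000,
    "dosage": "dup", "category": "scz_associated",
    "key_genes": [
      {"chrom": "chr16", "start": 30097001, "end": 30103000}
    ]
  },
  {
    "name": "16p13.11dup", "chrom": "chr16",
    "start": 15510001, "end": 16290000,
    "dosage": "dup", "category": "scz_associated",
    "key_genes": [
      {"chrom": "chr16", "start": 15737001, "end": 15820000}
    ]
  },
  {
    "name": "22q11.2del", "chrom": "chr22",
    "start": 19037001, "end": 21466000,
    "dosage": "del", "category": "scz_associated",
    "key_genes": [
      {"chrom": "chr22", "start": 19744001, "end": 19772000}
    ]
  },
  {
    "name": "16p12.1del", "chrom": "chr16",
    "start": 21950001, "end": 22430000,
    "dosage": "del", "category": "pathogenic_other"
  },
  {
    "name": "7q11.23del", "chrom": "chr7",
    "start": 72740001, "end": 74140000,
    "dosage": "del", "category": "pathogenic_other"
  },
  {
    "name": "17p11.2del", "chrom": "chr17",
    "start": 16820001, "end": 20210000,
    "dosage": "del", "category": "pathogenic_other"
  },
  {
    "name": "17q21.31del", "chrom": "chr17",
    "start": 43700001, "end": 44170000,
    "dosage": "del", "category": "pathogenic_other"
  },
  {
    "name": "22q13.3del", "chrom": "chr22",
    "start": 51120001, "end": 51200000,
    "dosage": "del", "category": "pathogenic_other"
  }
]
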