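{
  "amplicons": [
    {
      "id": "IDH1",
      "sequence": "CACTGAGAGTGGCAGTTGTGGACTGCGACGGCTTGGAAGCCATTCCCGTATCTGTCTCCCAGTCCATTACTGCACCAATTATAACATTGGGCACCAGGCATGAAATCACCCTAGGTCTATACTTTAAGATCCGTGGTATATAAAGTACACCAGTACCATTCAAGTTGCCCTAGTACGTATCTGAATACCGCGATATGGCTGGATCAGCTGTATATGTTAGGCAAGGCCCAGTATCGGCAGGTTCGTTAGCAGGCCATCACGGCGGGCCCTAAGTGAGTTGCGGGATAACTGGACGACCGGGGACATAAAGTACCCACCGTTCGCCGAGAGAATCGGAAACACCGTTTCTACCCGTAAGGAGACCTCACTTACGGAACCGCAGGACAACCAAAGATCTCAAGCGAAAATCACGTACGGTTATGAGGTTATACTGTGTTGATTGGCTTGCATTACGGTGTGCGCAGCTACATGAAGGCCCAGAGAATTGTC",
      "description": "synthetic placeholder amplicon for IDH1 hotspot region"
    },
    {
      "id": "IDH2",
      "sequence": "CGCTACACTGTACTGGCACAAATTCCGCTCTAGCGACCATTATAGCACCGTTGTTGGAGCCACTCGGGAAGGGGTGATTTTGCTTCTAAACCAAATATAACGCTTTGACCCTACGGGGTCGCCGGGTAGCATGACCTGATAGGATACTATCCCATATATATCAAAACATGGGTTACGCCAGTAATGATTGTGTGCATCGGGCACCCACAGTCACGCCCATAAATTTGTCAAAACTCTCTGACGTAAATACTAAGAGAATCGTCATAAGTCTGGTCTATCAGGTTTAGGTGGATTTGGAATCACGTGGAGCGAAAAATTCACGCGCTGCATAATTCCCCAATATCAAACGGGGGGTAGTTTCGCCCGCGACTTTTGGACCGCACGAAGCCCTTACGTCGAGTTTCAGAACCGAGATCACCATGAGGGTTTTAGATTAGGGGCACGCTAGTGGGACCGGGCCGTGATCGAGCAAAAGTCCTTTCAGGAGTAACACAACAAGTTTTCTGAGTCATACTTCTGT",
      "description": "synthetic placeholder amplicon for IDH2 hotspot region"
    },
    {
      "id": "TERT",
      "sequence": "CGGCCGACAGGTCTCACTGTCTGCGTCCCGGATCGTCAGCGGGCGCCCGGCTCCCAGCGGAGCGGGGGTGGACGGTCTTGGCCTGCCCCCGTCTGACCGGCCGCGACCGCAAGAGGGTCCCCGTGAAGGTGGCGGCTGGCAGGGAGCCGTCATGGCACGTCTCGCCACCTCGATTCCTGGCCGCGGAGGCGGCTGCCGCCTCCGCGCGTTGCGTGGGCCCCCACGGATTATCGCAGGGCCCCCCATATGCGGGACACGAGCAAAGGTCGTTGTTCCGGCCAGCGGCGGACCTACGGACCCCCCGGTGCTGCAGTCGCAAGGCGTACGTCCGCCCGCGGGGCTCGGCCCGCGTGCTGGGCCTGCCCCCTATCCCTTGCGCAAGGCCGGCGGGGAGTGTGTCGCCGCGGCACCCCGGCCGGATGCCTGCGAGAGTGCGGACCACGCCGGCACCCCGTCACTCCCCGGTGGCGGCCCCAGGGCGACCTACGCGTTAATGGTCTGCCGGCACGCCGACCACGCTCGCAGCACGCCCTGGCCGATCCAGTGAGCGGGGGAGGCCC",
      "description": "synthetic placeholder amplicon for TERT hotspot region"
    },
    {
      "id": "H3F3A",
      "sequence": "CTAAATACGACGCCGTACTGGTTACGGAGAACCGGAGCCCGGGGTGTTGATAACCGCGCAAGCTATAGGGAGTTTTCTGAGGTTAAGTTAAGGTCCTGGGTAAAGATAGCGGCTACGGGCCAGTCATTAGACGTCTACGCAGGCTATATACTCTCGGTCACCGGATTAGCCACTCGCTATAAGAGCCAATCACCACGCATTGGATTTGATCTAAGAGTTCAACTTCTCTCACAGGACAACACCAGCGGGAGTTTCTTTTCTGCAGCCAGCTGGGAGAATGATATATATCCACGGTAGAGGCTCGGGTGGTCGTTAGCAGGCGGGATTTCGTTCCACTCCGTTCCACTACAATTAACGCGGGAATGCAAGGCCTAGATTCTCGTTAGAGCTACCAAGCGGCATTGGTAATGCCAATTACGTATATCAGGCCTTCGTCTCACGTTACGAAGCGGCGCGGCCACCAGCCTGGCCAGAATTAAGCGAGCGATGGTCTTAGTTTGATCGTACACGGTACACTAGGGGTAACATATTGTTAACGGACATCCTCCCCATACTTGCTCTATTAGTGCGTTAGGTAGGTGTACGTGCCCACGTTGTCTG",
      "description": "synthetic placeholder amplicon for H3F3A hotspot region"
    },
    {
      "id": "HIST1H3B",
      "sequence": "AGTCGACAAAGCCGTTCCACAGTAGCTATCATAGACAAAATGTTATGAGCGCAATCATTGGCATCCTGGATAATGCTTTCACTAACACTGTAGCCTTTTCAGATACGTCATTAAGAATCTTTGGCGATAGTCCCATCAGCAATACTCTTGTCGGAAAACAAATAGTGCGCGCCGGTGTTGTGTTTTCCGCTTAGATCGGTTTCCTGCAGAGCTACTGTTCTAAAGAGGAGCTACCCCGACGATTGTCCCTTGTGTGTTAAATGATACGACTACTCCCGTCCAGTACGCGTTTTTCACTGCCCGAATCGGCACCGCTGTAGGCCACCGCCCTCGCATACGCATGTTGACCGGGGTGGCACCGAGTATACCCAGTTTAGGTCACAAGAACTCACGGCGGTGTTCGGACAACTTAGTGTCAGCATCGCTTACACTGCCATTGAACAACCTCAGCATGTGCGTCGGAACGGTCCACACCCAAAAACCTACCCGCAGAAAATACTGCCAGATTCCGAAATTTGTTCAATCAACTATACTATAGGACCCAATAACGTGGGCACGCGGCACTGGCTTCGGCCTCAACGTTTGGCCTTCAGCATCAATGCCTTTCGGCCAGTCGATTAAACGAGGAATATCTATACAT",
      "description": "synthetic placeholder amplicon for HIST1H3B hotspot region"
    },
    {
      "id": "BRAF",
      "sequence": "CTCCAGCTCCTACGTACCGGAACGATGACGACGAGTCGTTTGGCAAGTCGCTAGTATGCTCCTTCAGCCGGGCGCTTGGAACTGGTCAAGAACAAGCTCATATACAAGGGTAGACCGGTTTTGGTTCAGAATGTTTGTCTGTTAGCGCCTGGTTCTCAAGACGGCGGGCCGTGCCGTCGCTTGTAGGCAGCGATCTCTCGCTTCCAGTGAATAAACTAATAGCGCACCTAAGTAAACATTGACATCCTGCGAGGATTTAACTCCTTTAGAGTTTCTCCGGCTGCTTCGGTGCACGGAACGAACTAGATCTAAAGTTCACAGTTTCAAACGTGGTGTGCCAGTCTAGCCTAAGACGTGTGCTATCGTCCAGGAGCTCGGATAGTGTCCACGTAGGTATCGACCGGGGGGCCTAACTCTACAAGCGACCCCAAAGGTAAACAGGATGTAGCCGCCCTAAGAGTGCCGCTGGCGGATGTCCCACCGTCGAGTAGTCAACTGTACATGTTTATGTAATCTTTTTCGCTTCTAAGAGACATCACTAATTCGGGTCCCTGACCACCGGACGACACTTATGAATGGCCGCTTGAGCTACTGTTGAGATCGCAAAACGTACACTAGGCCCAAACCGCACGTGCGACTTATTTCTGCTCGAATTTGCTCACGGGTGCGAAACGGGATGT",
      "description": "synthetic placeholder amplicon for BRAF hotspot region"
    }
  ],
  "markers": [
    {
      "marker_id": "IDH1_R132H",
      "amplicon_id": "IDH1",
      "offset": 244,
      "width": 1,
      "wt_allele": "G",
      "mut_alleles": {
        "R132H": "A"
      }
    },
    {
      "marker_id": "IDH2_R172K",
      "amplicon_id": "IDH2",
      "offset": 260,
      "width": 1,
      "wt_allele": "G",
      "mut_alleles": {
        "R172K": "A"
      }
    },
    {
      "marker_id": "TERT_C228T",
      "amplicon_id": "TERT",
      "offset": 260,
      "width": 1,
      "wt_allele": "C",
      "mut_alleles": {
        "C228T": "T"
      }
    },
    {
      "marker_id": "TERT_C250T",
      "amplicon_id": "TERT",
      "offset": 282,
      "width": 1,
      "wt_allele": "C",
      "mut_alleles": {
        "C250T": "T"
      }
    },
    {
      "marker_id": "H3F3A_K27M",
      "amplicon_id": "H3F3A",
      "offset": 290,
      "width": 1,
      "wt_allele": "A",
      "mut_alleles": {
        "K27M": "T"
      }
    },
    {
      "marker_id": "H3F3A_G34R",
      "amplicon_id": "H3F3A",
      "offset": 311,
      "width": 1,
      "wt_allele": "G",
      "mut_alleles": {
        "G34R": "A"
      }
    },
    {
      "marker_id": "HIST1H3B_K27M",
      "amplicon_id": "HIST1H3B",
      "offset": 310,
      "width": 1,
      "wt_allele": "A",
      "mut_alleles": {
        "K27M": "T"
      }
    },
    {
      "marker_id": "BRAF_V600E",
      "amplicon_id": "BRAF",
      "offset": 330,
      "width": 1,
      "wt_allele": "T",
      "mut_alleles": {
        "V600E": "A"
      }
    }
  ],
  "k_default": 1,
  "flank": 10
}
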