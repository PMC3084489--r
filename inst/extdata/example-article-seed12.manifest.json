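{
  "seed": 12,
  "meta": {
    "authors": [
      {
        "surname": "Zudrute",
        "given": "G N"
      },
      {
        "surname": "Thaethiatrio",
        "given": "Z"
      },
      {
        "surname": "Pliatruleo",
        "given": "T Z"
      }
    ],
    "year": 2011,
    "title": "New and poorly known species of Susiazaeum from synthetic localities",
    "journal": "ZooKeys",
    "issue_no": "93",
    "pages": "20-51",
    "doi": "10.9999/synthetic.113.1132",
    "publication_date": "2011-03-18"
  },
  "treatments": [
    {
      "genus": "Drioplious",
      "species_epithet": "runulaeensis",
      "authorship": "Pliatruleo, 2011",
      "zoobank_lsid": "urn:lsid:zoobank.org:act:014CB5D8",
      "classification": {
        "order": "Brialeoida",
        "family": "Plosuidae"
      },
      "section_labels": ["Type locality", "Description", "Diagnosis", "Ecology"],
      "n_figures": 2,
      "n_references": 2,
      "key_shape": {}
    },
    {
      "genus": "Pliobriokiaa",
      "species_epithet": "riguraeae",
      "authorship": "Pliatruleo, 2011",
      "zoobank_lsid": "urn:lsid:zoobank.org:act:01F87D9D",
      "classification": {
        "order": "Zerioida",
        "family": "Bipiidae"
      },
      "section_labels": ["Type locality", "Description", "Distribution", "Etymology"],
      "n_figures": 0,
      "n_references": 1,
      "key_shape": {}
    },
    {
      "genus": "Drioplious",
      "species_epithet": "hiothiceatus",
      "authorship": "Zudrute, 2011",
      "zoobank_lsid": "urn:lsid:zoobank.org:act:01A7ACAA",
      "classification": {
        "order": "Keothiaida",
        "family": "Bubiidae"
      },
      "section_labels": ["Type locality", "Distribution", "Ecology", "Materials examined"],
      "n_figures": 2,
      "n_references": 3,
      "key_shape": {
        "n_couplets": 3,
        "n_leads": 6
      }
    },
    {
      "genus": "Pliobriokiaa",
      "species_epithet": "keosoicus",
      "authorship": "Zudrute, 2011",
      "zoobank_lsid": "urn:lsid:zoobank.org:act:0127A64B",
      "classification": {
        "order": "Faediida",
        "family": "Domoidae"
      },
      "section_labels": ["Type locality", "Description", "Diagnosis", "Remarks"],
      "n_figures": 2,
      "n_references": 1,
      "key_shape": {}
    }
  ]
}
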