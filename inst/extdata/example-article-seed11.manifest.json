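{
  "seed": 11,
  "meta": {
    "authors": [
      {
        "surname": "Platruzae",
        "given": "N C"
      },
      {
        "surname": "Brucrikia",
        "given": "K"
      },
      {
        "surname": "Ciochia",
        "given": "L B"
      }
    ],
    "year": 2011,
    "title": "New and poorly known species of Piociamious from synthetic localities",
    "journal": "PhytoKeys",
    "issue_no": "16",
    "pages": "10-31",
    "doi": "10.9999/synthetic.14.5305",
    "publication_date": "2011-05-20"
  },
  "treatments": [
    {
      "genus": "Cheziacraus",
      "species_epithet": "haebraezuatus",
      "authorship": "Ciochia, 2011",
      "zoobank_lsid": "urn:lsid:zoobank.org:act:00FDBD8C",
      "classification": {
        "order": "Chabioida",
        "family": "Thiphioidae"
      },
      "section_labels": ["Distribution", "Etymology", "Materials examined", "Remarks"],
      "n_figures": 2,
      "n_references": 1,
      "key_shape": {}
    },
    {
      "genus": "Cheziacraus",
      "species_epithet": "piphiicus",
      "authorship": "Platruzae, 2011",
      "zoobank_lsid": "urn:lsid:zoobank.org:act:008CDB3F",
      "classification": {
        "order": "Treoceida",
        "family": "Zioniidae"
      },
      "section_labels": ["Type locality", "Diagnosis", "Ecology", "Materials examined"],
      "n_figures": 2,
      "n_references": 2,
      "key_shape": {}
    }
  ]
}
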