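[
  {
    "id": "R00025",
    "annotation": "2-nitropropane dioxygenase; EC 1.13.12.16; RC00126/RC02541/RC02759",
    "substrates": [
      {
        "id": "C05985",
        "name": "ethylnitronate",
        "formula": "C2H4NO2",
        "mass": 74.0242
      },
      {
        "id": "C00007",
        "name": "oxygen",
        "formula": "O2",
        "mass": 31.9898
      },
      {
        "id": "C01847",
        "name": "reduced FMN",
        "formula": "C17H23N4O9P",
        "mass": 458.1202
      }
    ],
    "products": [
      {
        "id": "C00084",
        "name": "acetaldehyde",
        "formula": "C2H4O",
        "mass": 44.0262
      },
      {
        "id": "C00088",
        "name": "nitrite",
        "formula": "HNO2",
        "mass": 47.0007
      },
      {
        "id": "C00061",
        "name": "FMN",
        "formula": "C17H21N4O9P",
        "mass": 456.1046
      },
      {
        "id": "C00001",
        "name": "water",
        "formula": "H2O",
        "mass": 18.0105
      }
    ]
  }
]
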