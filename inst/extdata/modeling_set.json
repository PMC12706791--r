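{
  "version": "1.0",
  "note": "Catalog of the 76-compound modeling set (ids + subtype codes). Ids not named in the running text are inferred from the sequential-numbering scheme; the catalog carries no shift data.",
  "compounds": [
    {
      "id": "A20-1",
      "name": null
    },
    {
      "id": "A20-2",
      "name": "toxyloxanthone E"
    },
    {
      "id": "A20-4",
      "name": null
    },
    {
      "id": "A20-6",
      "name": null
    },
    {
      "id": "A20-7",
      "name": null
    },
    {
      "id": "A23-1",
      "name": null
    },
    {
      "id": "A23-2",
      "name": null
    },
    {
      "id": "A23-3",
      "name": "cudraxanthone B"
    },
    {
      "id": "A23-4",
      "name": null
    },
    {
      "id": "A23-5",
      "name": null
    },
    {
      "id": "A23-6",
      "name": "garcinone B"
    },
    {
      "id": "A23-7",
      "name": null
    },
    {
      "id": "A23-8",
      "name": "allanxanthone B"
    },
    {
      "id": "A23-9",
      "name": null
    },
    {
      "id": "A23-11",
      "name": null
    },
    {
      "id": "A23-12",
      "name": null
    },
    {
      "id": "A23-13",
      "name": null
    },
    {
      "id": "A23-15",
      "name": "calotetrapterin D"
    },
    {
      "id": "A23-16",
      "name": "calotetrapterin E"
    },
    {
      "id": "A23-17",
      "name": "calotetrapterin A"
    },
    {
      "id": "B13-1",
      "name": null
    },
    {
      "id": "B13-2",
      "name": "garciosone E"
    },
    {
      "id": "B31-1",
      "name": null
    },
    {
      "id": "B31-2",
      "name": null
    },
    {
      "id": "B31-3",
      "name": "6-deoxyjacareubin"
    },
    {
      "id": "B31-4",
      "name": null
    },
    {
      "id": "B31-5",
      "name": null
    },
    {
      "id": "B31-6",
      "name": null
    },
    {
      "id": "B31-7",
      "name": null
    },
    {
      "id": "B31-8",
      "name": null
    },
    {
      "id": "B31-9",
      "name": "inoxanthone"
    },
    {
      "id": "B31-10",
      "name": "macluraxanthone"
    },
    {
      "id": "B31-11",
      "name": null
    },
    {
      "id": "B31-12",
      "name": "calabaxanthone"
    },
    {
      "id": "B31-13",
      "name": "3-isomangostin"
    },
    {
      "id": "B31-14",
      "name": null
    },
    {
      "id": "B31-16",
      "name": null
    },
    {
      "id": "B31-18",
      "name": null
    },
    {
      "id": "B34-1",
      "name": null
    },
    {
      "id": "B34-2",
      "name": null
    },
    {
      "id": "B34-3",
      "name": null
    },
    {
      "id": "B34-4",
      "name": null
    },
    {
      "id": "B34-5",
      "name": "pedunxanthone C"
    },
    {
      "id": "C21-1",
      "name": null
    },
    {
      "id": "C21-2",
      "name": null
    },
    {
      "id": "C21-3",
      "name": null
    },
    {
      "id": "C24-1",
      "name": null
    },
    {
      "id": "C24-2",
      "name": null
    },
    {
      "id": "C40-1",
      "name": null
    },
    {
      "id": "C40-2",
      "name": null
    },
    {
      "id": "D31-1",
      "name": null
    },
    {
      "id": "D31-2",
      "name": null
    },
    {
      "id": "D31-3",
      "name": null
    },
    {
      "id": "D31-4",
      "name": null
    },
    {
      "id": "D31-5",
      "name": null
    },
    {
      "id": "D31-6",
      "name": null
    },
    {
      "id": "D31-8",
      "name": null
    },
    {
      "id": "D31-9",
      "name": null
    },
    {
      "id": "D31-10",
      "name": null
    },
    {
      "id": "D31-11",
      "name": null
    },
    {
      "id": "D31-12",
      "name": "cudratricusxanthone H"
    },
    {
      "id": "D31-13",
      "name": null
    },
    {
      "id": "D31-15",
      "name": null
    },
    {
      "id": "D31-16",
      "name": "demethylsterigmatocystin"
    },
    {
      "id": "D31-17",
      "name": "morusignin H"
    },
    {
      "id": "D31-18",
      "name": "pruniflorone N"
    },
    {
      "id": "D32-1",
      "name": "nigrolineaxanthone H"
    },
    {
      "id": "D32-2",
      "name": null
    },
    {
      "id": "D32-3",
      "name": null
    },
    {
      "id": "D32-4",
      "name": null
    },
    {
      "id": "A20-3-B31-17",
      "name": "thwaitesixanthone"
    },
    {
      "id": "A20-5-D31-7",
      "name": "cudraxanthone A"
    },
    {
      "id": "A23-10-B34-9",
      "name": null
    },
    {
      "id": "A23-14-B31-20",
      "name": "calophinone"
    },
    {
      "id": "B31-15-B34-6",
      "name": "pyranojacareubin"
    },
    {
      "id": "B31-19-D32-5",
      "name": "mangostenone A"
    }
  ]
}
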