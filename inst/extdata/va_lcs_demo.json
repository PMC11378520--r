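{
  "resources": [
    {
      "id": "NN",
      "description": "Nurse navigator: tracks screened patients and follows up results"
    },
    {
      "id": "PCP",
      "description": "Primary care provider: gatekeeper for screening"
    },
    {
      "id": "Radiologist",
      "description": "Radiologist: reads low-dose CT scans"
    }
  ],
  "tasks": [
    {
      "id": "1",
      "label": "Computer checks eligibility of VA population",
      "minutes": [],
      "outcomes": [
        {
          "next": "2",
          "percent": 30
        },
        {
          "next": "3",
          "percent": 70
        }
      ]
    },
    {
      "id": "2",
      "label": "PCP discusses screening and offers smoking cessation",
      "minutes": {
        "PCP": 3
      },
      "outcomes": [
        {
          "next": "3",
          "percent": 40
        },
        {
          "next": "5",
          "percent": 60
        }
      ]
    },
    {
      "id": "3",
      "label": "NN offers smoking cessation",
      "minutes": {
        "NN": 1
      },
      "outcomes": [
        {
          "next": "4",
          "percent": 60
        },
        {
          "next": "13",
          "percent": 40
        }
      ]
    },
    {
      "id": "4",
      "label": "PCP connects to smoking cessation program",
      "minutes": {
        "PCP": 1
      },
      "outcomes": [
        {
          "next": "13",
          "percent": 100
        }
      ]
    },
    {
      "id": "5",
      "label": "PCP schedules LDCT",
      "minutes": {
        "PCP": 2
      },
      "outcomes": [
        {
          "next": "6",
          "percent": 10
        },
        {
          "next": "7",
          "percent": 90
        }
      ]
    },
    {
      "id": "6",
      "label": "NN follows up",
      "minutes": {
        "NN": 5
      },
      "outcomes": [
        {
          "next": "7",
          "percent": 75
        },
        {
          "next": "13",
          "percent": 25
        }
      ]
    },
    {
      "id": "7",
      "label": "Radiologist conducts LDCT",
      "minutes": {
        "Radiologist": 10
      },
      "outcomes": [
        {
          "next": "8",
          "percent": 0.5
        },
        {
          "next": "9",
          "percent": 49.6
        },
        {
          "next": "10",
          "percent": 41.8
        },
        {
          "next": "11",
          "percent": 3.4
        },
        {
          "next": "12",
          "percent": 4.7
        }
      ]
    },
    {
      "id": "8",
      "label": "LungRADS 0: radiologist conducts additional LDCT",
      "minutes": {
        "Radiologist": 10
      },
      "outcomes": [
        {
          "next": "13",
          "percent": 100
        }
      ]
    },
    {
      "id": "9",
      "label": "LungRADS 1a/2a/2b: PCP and NN follow up to continue annual LDCT",
      "minutes": {
        "NN": 10
      },
      "outcomes": [
        {
          "next": "13",
          "percent": 100
        }
      ]
    },
    {
      "id": "10",
      "label": "LungRADS 3a: NN follows up",
      "minutes": {
        "NN": 10
      },
      "outcomes": [
        {
          "next": "13",
          "percent": 100
        }
      ]
    },
    {
      "id": "11",
      "label": "LungRADS 4a/4b/4x: NN follows up",
      "minutes": {
        "NN": 10
      },
      "outcomes": [
        {
          "next": "13",
          "percent": 100
        }
      ]
    },
    {
      "id": "12",
      "label": "LungRADS S: NN notifies PCP for follow up",
      "minutes": {
        "NN": 10
      },
      "outcomes": [
        {
          "next": "13",
          "percent": 100
        }
      ]
    },
    {
      "id": "13",
      "label": "Patients complete one cycle of screening in the program",
      "minutes": [],
      "outcomes": []
    }
  ],
  "root": "1",
  "population": 75000
}
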