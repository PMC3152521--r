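# Topology of the insomnia treatment-pathway tree (seek-treatment subtree).
# Branch probabilities below the first-contact split are not published and
# must be supplied by a probability completion; `p` is therefore omitted
# everywhere except the root. Event ids reference rows of utilisation.csv.
name: NZ insomnia treatment pathways
currency_year: 2009
root:
  id: seek
  kind: chance
  p: 1.0
  event: seek
  children:
  - id: '1'
    kind: chance
    event: '1'
    children:
    - id: '1.1'
      kind: end
      event: '1.1'
    - id: '1.2'
      kind: end
      event: '1.2'
  - id: '2'
    kind: chance
    event: '2'
    children:
    - id: '2.1'
      kind: end
      event: '2.1'
    - id: '2.2'
      kind: chance
      event: '2.2'
      children:
      - id: '2.2.1'
        kind: end
        event: '2.2.1'
      - id: '2.2.2'
        kind: chance
        event: '2.2.2'
        children:
        - id: '2.2.2.1'
          kind: end
          event: '2.2.2.1'
        - id: '2.2.2.2'
          kind: end
          event: '2.2.2.2'
        - id: '2.2.2.3'
          kind: end
          event: '2.2.2.3'
  - id: '3'
    kind: chance
    event: '3'
    children:
    - id: '3.1'
      kind: end
      event: '3.1'
    - id: '3.2'
      kind: chance
      event: '3.2'
      children:
      - id: '3.2.1'
        kind: end
        event: '3.2.1'
      - id: '3.2.2'
        kind: chance
        event: '3.2.2'
        children:
        - id: '3.2.2.1'
          kind: end
          event: '3.2.2.1'
        - id: '3.2.2.2'
          kind: end
          event: '3.2.2.2'
        - id: '3.2.2.3'
          kind: end
          event: '3.2.2.3'
        - id: '3.2.2.4'
          kind: end
          event: '3.2.2.4'
  - id: '4'
    kind: chance
    event: '4'
    children:
    - id: '4.1'
      kind: end
      event: '4.1'
    - id: '4.2'
      kind: chance
      event: '4.2'
      children:
      - id: '4.2.1'
        kind: end
        event: '4.2.1'
      - id: '4.2.2'
        kind: chance
        event: '4.2.2'
        children:
        - id: '4.2.2.1'
          kind: end
          event: '4.2.2.1'
        - id: '4.2.2.2'
          kind: end
          event: '4.2.2.2'
        - id: '4.2.2.3'
          kind: end
          event: '4.2.2.3'
        - id: '4.2.2.4'
          kind: end
          event: '4.2.2.4'
  - id: '5'
    kind: chance
    event: '5'
    children:
    - id: '5.1'
      kind: end
      event: '5.1'
    - id: '5.2'
      kind: chance
      event: '5.2'
      children:
      - id: '5.2.2'
        kind: end
        event: '5.2.2'
      - id: '5.2.3'
        kind: chance
        event: '5.2.3'
        children:
        - id: '5.2.3.1'
          kind: end
          event: '5.2.3.1'
        - id: '5.2.3.2'
          kind: end
          event: '5.2.3.2'
        - id: '5.2.3.3'
          kind: end
          event: '5.2.3.3'
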