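<?xml version="1.0" encoding="UTF-8"?>
<DataSheet>
  <Header ncols="3" nrows="2">
    <Column id="1" name="Name" type="string"/>
    <Column id="2" name="BoilingPoint" type="real"/>
    <Column id="3" name="Density" type="real"/>
    <Extension name="Solvent">column=BoilingPoint;role=temperature;units=degC;type=real
column=Density;role=density;units=g/mL;type=real</Extension>
  </Header>
  <Row id="1">
    <Cell col="1">water</Cell>
    <Cell col="2">100</Cell>
    <Cell col="3">0.997</Cell>
  </Row>
  <Row id="2">
    <Cell col="1">ethanol</Cell>
    <Cell col="2">78.4</Cell>
    <Cell col="3">0.789</Cell>
  </Row>
</DataSheet>

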