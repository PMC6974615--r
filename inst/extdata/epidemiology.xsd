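<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">

  <xs:simpleType name="levelType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="group"/>
      <xs:enumeration value="disorder"/>
      <xs:enumeration value="subtype"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="indicatorType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="point_prevalence"/>
      <xs:enumeration value="birth_prevalence"/>
      <xs:enumeration value="lifetime_prevalence"/>
      <xs:enumeration value="annual_incidence"/>
      <xs:enumeration value="case_report"/>
      <xs:enumeration value="family_report"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="valueKindType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="numeric"/>
      <xs:enumeration value="class"/>
      <xs:enumeration value="count"/>
      <xs:enumeration value="unknown"/>
      <xs:enumeration value="not_documented"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="classType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="lt_1_per_1M"/>
      <xs:enumeration value="from_1_to_9_per_1M"/>
      <xs:enumeration value="from_1_to_9_per_100k"/>
      <xs:enumeration value="from_1_to_5_per_10k"/>
      <xs:enumeration value="from_6_to_9_per_10k"/>
      <xs:enumeration value="gt_1_per_1k"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="regionType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="worldwide"/>
      <xs:enumeration value="europe"/>
      <xs:enumeration value="usa"/>
      <xs:enumeration value="other"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:complexType name="geographyType">
    <xs:simpleContent>
      <xs:extension base="regionType">
        <xs:attribute name="area" type="xs:string" use="required"/>
      </xs:extension>
    </xs:simpleContent>
  </xs:complexType>

  <xs:element name="EpidemiologyData">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="DisorderList">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="Disorder" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="Name" type="xs:string"/>
                    <xs:element name="Level" type="levelType"/>
                    <xs:element name="DomainFlags" type="xs:string"/>
                    <xs:element name="OnsetTags" type="xs:string"/>
                    <xs:element name="InheritanceTags" type="xs:string"/>
                  </xs:sequence>
                  <xs:attribute name="id" type="xs:positiveInteger" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="count" type="xs:nonNegativeInteger"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="PrevalenceList">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="Prevalence" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="Indicator" type="indicatorType"/>
                    <xs:element name="ValueKind" type="valueKindType"/>
                    <xs:choice minOccurs="0">
                      <xs:element name="ValuePer100k" type="xs:decimal"/>
                      <xs:element name="Class" type="classType"/>
                      <xs:element name="Count" type="xs:nonNegativeInteger"/>
                    </xs:choice>
                    <xs:element name="Geography" type="geographyType"/>
                  </xs:sequence>
                  <xs:attribute name="disorder" type="xs:positiveInteger" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="count" type="xs:nonNegativeInteger"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="version" type="xs:string"/>
    </xs:complexType>
  </xs:element>

</xs:schema>
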