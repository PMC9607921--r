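<?xml version="1.0" encoding="UTF-8"?>
<!-- Strict schema for the extract wire dialect, version 1.
     Kind-conditional attribute rules (conceptId/schemeUri/codeUri only for
     kind="coded", unit only for kind="quantity") are XSD 1.1 territory and
     are enforced by the parsing layer instead. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           targetNamespace="urn:ehr13606:extract:1"
           xmlns:e="urn:ehr13606:extract:1"
           elementFormDefault="qualified"
           attributeFormDefault="unqualified">

  <xs:simpleType name="nonEmptyString">
    <xs:restriction base="xs:string">
      <xs:minLength value="1"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="valueKind">
    <xs:restriction base="xs:string">
      <xs:enumeration value="coded"/>
      <xs:enumeration value="date"/>
      <xs:enumeration value="quantity"/>
      <xs:enumeration value="text"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="nodeId">
    <xs:restriction base="xs:string">
      <xs:pattern value="at[0-9]{4}"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="ehrExtract">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="entry" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="element" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="value">
                      <xs:complexType>
                        <xs:simpleContent>
                          <xs:extension base="xs:string">
                            <xs:attribute name="kind" type="e:valueKind" use="required"/>
                            <xs:attribute name="conceptId" type="e:nonEmptyString"/>
                            <xs:attribute name="schemeUri" type="xs:anyURI"/>
                            <xs:attribute name="codeUri" type="xs:anyURI"/>
                            <xs:attribute name="unit" type="e:nonEmptyString"/>
                          </xs:extension>
                        </xs:simpleContent>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                  <xs:attribute name="nodeId" type="e:nodeId" use="required"/>
                  <xs:attribute name="name" type="e:nonEmptyString" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="archetypeId" type="e:nonEmptyString" use="required"/>
            <xs:attribute name="rcId" type="e:nonEmptyString"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="extractId" type="e:nonEmptyString" use="required"/>
      <xs:attribute name="subjectId" type="e:nonEmptyString" use="required"/>
      <xs:attribute name="timeCreated" use="required">
        <xs:simpleType>
          <xs:restriction base="xs:string">
            <xs:pattern value="[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}Z"/>
          </xs:restriction>
        </xs:simpleType>
      </xs:attribute>
    </xs:complexType>
  </xs:element>
</xs:schema>
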